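id	signal_end	propeptide_end	notes
PLP1	16	28	synthetic signal+spacer; published mature region
PLP2	16	28	synthetic signal+spacer; published mature region
PLP3	16	28	synthetic signal+spacer; published mature region
PLP4	16	28	synthetic signal+spacer; published mature region
PLP5	16	28	synthetic signal+spacer; published mature region
PLP6	16	28	synthetic signal+spacer; published mature region
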