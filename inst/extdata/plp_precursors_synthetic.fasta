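>PLP1 synthetic scaffold + published mature region
MKPSLLLALLFVAVLAEAEPEAEADAEPGILDWGKKVMDWIKDKMGK
>PLP2 synthetic scaffold + published mature region
MKPSLLLALLFVAVLAEAEPEAEADAEPGWGSIFKTVGKMIAKAAVKAAPEAISAMASQNEK
>PLP3 synthetic scaffold + published mature region
MKPSLLLALLFVAVLAEAEPEAEADAEPKIKWGKIFKKGGKLIGKTALEAAANAAASEAISAMASQNEK
>PLP4 synthetic scaffold + published mature region
MKPSLLLALLFVAVLAEAEPEAEADAEPGVKELFGKAWGLVKKHLPKACGLLGYVKQ
>PLP5 synthetic scaffold + published mature region
MKPSLLLALLFVAVLAEAEPEAEADAEPIWGALLGTLIPAITSAIQGK
>PLP6 synthetic scaffold + published mature region
MKPSLLLALLFVAVLAEAEPEAEADAEPIKGKKIMKNMGKAMKIAGKVAKAMAPIVVPLIVSAAGK
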