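label,mass,rt,area
Om3264,3263.957,10.58,0.41
Om4117,4117.238,11.04,0.25
Om3489,3488.881,13.84,0.46
Om4229,4229.334,14.45,NA
Om3101,3100.615,14.45,NA
Om4101,4101.244,15.04,12.94
Om3704,3704.235,16.51,4.29
Om4401,4401.364,17.51,0.26
Om6368,6367.557,23.07,20.85
Om6350,6349.589,23.99,5.27
Om6332,6331.631,24.62,5.42
Om3362,3361.756,25.37,7.78
Om3325,3324.856,26.94,6.97
Om2247,2247.188,27.66,1.52
Om2119,2119.094,29.26,NA
Om2061,2061.089,29.76,27.41
Om1782,1782.019,32.05,1.08
Om1812,1812.03,33.62,0.67
Om1837,1836.995,34.86,3.65
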