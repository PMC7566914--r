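strain,gene,mean_ct,sd_ct,n,p_value
CCMP0999,tef1a,19.2,0.5,6,4.64E-03
CCMP0999,petF,18.2,0.1,6,-
CCMP0999,rbcS,14.6,0.1,6,2.12E-09
CCMP1001,tef1a,23.1,0.9,6,1.48E-02
CCMP1001,petF,21.5,0.3,6,-
CCMP1001,rbcS,15.5,0.4,6,8.81E-10
CCMP1005,tef1a,19.9,0.4,6,2.83E-06
CCMP1005,petF,16.6,0.1,6,-
CCMP1005,rbcS,12.2,0.2,6,9.49E-09
CCMP1006,tef1a,19.6,0.3,6,1.04E-02
CCMP1006,petF,18.8,0.1,6,-
CCMP1006,rbcS,14.3,0.0,6,3.20E-08
CCMP1616,tef1a,,,0,
CCMP1616,petF,,,0,
CCMP1616,rbcS,,,0,
CCMP1012,tef1a,17.9,0.2,6,1.21E-08
CCMP1012,petF,15.5,0.2,6,-
CCMP1012,rbcS,15.6,0.1,6,1.95E-01
CCMP1013,tef1a,18.6,0.5,6,2.67E-05
CCMP1013,petF,14.4,0.2,6,-
CCMP1013,rbcS,14.5,0.1,6,1.80E-01
CCMP1014,tef1a,16.7,0.2,6,5.50E-07
CCMP1014,petF,15.1,0.6,6,-
CCMP1014,rbcS,15.4,0.5,6,8.48E-02
CCMP1335,tef1a,16.8,0.8,6,1.97E-04
CCMP1335,petF,14.0,0.6,6,-
CCMP1335,rbcS,14.2,0.3,6,6.58E-01
CCMP1010,tef1a,18.8,0.2,6,1.15E-07
CCMP1010,petF,14.2,0.0,6,-
CCMP1010,rbcS,14.3,0.1,6,1.79E-02
CCMP1049,tef1a,19.6,1.2,6,2.70E-05
CCMP1049,petF,14.9,0.5,6,-
CCMP1049,rbcS,14.9,0.5,6,2.40E-01
CCMP1052,tef1a,19.2,0.2,6,1.23E-13
CCMP1052,petF,11.2,0.2,6,-
CCMP1052,rbcS,12.1,0.3,6,9.09E-07
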