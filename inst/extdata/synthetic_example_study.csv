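"time_pct_rr","basal_anterior","basal_anteroseptal","basal_inferoseptal","basal_inferior","basal_inferolateral","basal_anterolateral","mid_anterior","mid_anteroseptal","mid_inferoseptal","mid_inferior","mid_inferolateral","mid_anterolateral","apical_anterior","apical_septal","apical_inferior","apical_lateral"
0,13.3652892736268,13.3652892736268,13.3652892736268,15.47,15.47,15.47,11.9,11.9,11.9,11.9,11.9,11.9,6.545,6.545,6.545,6.545
5,12.699052612217,12.699052612217,12.699052612217,15.3314607491705,15.3314607491705,15.3314607491705,11.7934313455158,11.7934313455158,11.7934313455158,11.7934313455158,11.7934313455158,11.7934313455158,6.48638724003369,6.48638724003369,6.48638724003369,6.48638724003369
10,12.1775890702376,12.1775890702376,12.1775890702376,14.9369343417595,14.9369343417595,14.9369343417595,11.4899494936612,11.4899494936612,11.4899494936612,11.4899494936612,11.4899494936612,11.4899494936612,6.31947222151364,6.31947222151364,6.31947222151364,6.31947222151364
15,11.8802867448762,11.8802867448762,11.8802867448762,14.3464838469045,14.3464838469045,14.3464838469045,11.0357568053111,11.0357568053111,11.0357568053111,11.0357568053111,11.0357568053111,11.0357568053111,6.06966624292112,6.06966624292112,6.06966624292112,6.06966624292112
20,11.8399701504297,11.8399701504297,11.8399701504297,13.65,13.65,13.65,10.5,10.5,10.5,10.5,10.5,10.5,5.775,5.775,5.775,5.775
25,11.9508836237751,11.9508836237751,11.9508836237751,12.9535161530955,12.9535161530955,12.9535161530955,9.96424319468887,9.96424319468887,9.96424319468887,9.96424319468887,9.96424319468887,9.96424319468887,5.48033375707888,5.48033375707888,5.48033375707888,5.48033375707888
30,12.1775890702376,12.1775890702376,12.1775890702376,12.3630656582405,12.3630656582405,12.3630656582405,9.51005050633883,9.51005050633883,9.51005050633883,9.51005050633883,9.51005050633883,9.51005050633883,5.23052777848636,5.23052777848636,5.23052777848636,5.23052777848636
35,12.5046368882893,12.5046368882893,12.5046368882893,11.9685392508295,11.9685392508295,11.9685392508295,9.2065686544842,9.2065686544842,9.2065686544842,9.2065686544842,9.2065686544842,9.2065686544842,5.06361275996631,5.06361275996631,5.06361275996631,5.06361275996631
40,12.909739309602,12.909739309602,12.909739309602,11.83,11.83,11.83,9.1,9.1,9.1,9.1,9.1,9.1,5.005,5.005,5.005,5.005
45,13.3652892736268,13.3652892736268,13.3652892736268,11.8920149961539,11.8920149961539,11.8920149961539,9.1477038431953,9.1477038431953,9.1477038431953,9.1477038431953,9.1477038431953,9.1477038431953,5.03123711375742,5.03123711375742,5.03123711375742,5.03123711375742
50,13.8402418031471,13.8402418031471,13.8402418031471,12.0738337651123,12.0738337651123,12.0738337651123,9.28756443470179,9.28756443470179,9.28756443470179,9.28756443470179,9.28756443470179,9.28756443470179,5.10816043908598,5.10816043908598,5.10816043908598,5.10816043908598
55,14.3022296681724,14.3022296681724,14.3022296681724,12.3630656582405,12.3630656582405,12.3630656582405,9.51005050633883,9.51005050633883,9.51005050633883,9.51005050633883,9.51005050633883,9.51005050633883,5.23052777848636,5.23052777848636,5.23052777848636,5.23052777848636
60,14.7197691591723,14.7197691591723,14.7197691591723,12.74,12.74,12.74,9.8,9.8,9.8,9.8,9.8,9.8,5.39,5.39,5.39,5.39
65,15.0644056498517,15.0644056498517,15.0644056498517,13.1789493379134,13.1789493379134,13.1789493379134,10.1376533368565,10.1376533368565,10.1376533368565,10.1376533368565,10.1376533368565,10.1376533368565,5.57570933527106,5.57570933527106,5.57570933527106,5.57570933527106
70,15.3126527329095,15.3126527329095,15.3126527329095,13.65,13.65,13.65,10.5,10.5,10.5,10.5,10.5,10.5,5.775,5.775,5.775,5.775
75,15.4475927798832,15.4475927798832,15.4475927798832,14.1210506620866,14.1210506620866,14.1210506620866,10.8623466631435,10.8623466631435,10.8623466631435,10.8623466631435,10.8623466631435,10.8623466631435,5.97429066472894,5.97429066472894,5.97429066472894,5.97429066472894
80,15.4475927798832,15.4475927798832,15.4475927798832,14.56,14.56,14.56,11.2,11.2,11.2,11.2,11.2,11.2,6.16,6.16,6.16,6.16
85,15.2018050991244,15.2018050991244,15.2018050991244,14.9369343417595,14.9369343417595,14.9369343417595,11.4899494936612,11.4899494936612,11.4899494936612,11.4899494936612,11.4899494936612,11.4899494936612,6.31947222151364,6.31947222151364,6.31947222151364,6.31947222151364
90,14.7197691591723,14.7197691591723,14.7197691591723,15.2261662348877,15.2261662348877,15.2261662348877,11.7124355652982,11.7124355652982,11.7124355652982,11.7124355652982,11.7124355652982,11.7124355652982,6.44183956091402,6.44183956091402,6.44183956091402,6.44183956091402
95,14.0748705622177,14.0748705622177,14.0748705622177,15.4079850038461,15.4079850038461,15.4079850038461,11.8522961568047,11.8522961568047,11.8522961568047,11.8522961568047,11.8522961568047,11.8522961568047,6.51876288624258,6.51876288624258,6.51876288624258,6.51876288624258
100,13.3652892736268,13.3652892736268,13.3652892736268,15.47,15.47,15.47,11.9,11.9,11.9,11.9,11.9,11.9,6.545,6.545,6.545,6.545
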