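"fat","leptin"
0.566768556290162,0.579910909908968
0.344305633392169,0.249054401125869
0.260897050239877,0.186789453084335
0.4478963950168,0.429905041605517
0.362955812806307,0.270541624256427
0.61453819048957,0.558566210249554
0.322285069730133,0.190984102854497
0.512914729389587,0.587618564376482
0.353220044697136,0.293791894317241
0.752042751066197,0.896233418065278
0.704797987799229,0.886917527049593
0.403060032897532,0.291643192323451
0.447717997492792,0.376386800360576
0.371111669586591,0.26875829243748
0.693273375795543,0.593234507725938
0.528001209867146,0.575662626289182
0.426913337741076,0.413646265655634
0.568870030961659,0.670520746984271
0.299100556326623,0.226862062144051
0.373366083770157,0.296010322879888
0.458671996460234,0.420828181783576
0.546070275665848,0.471825060325532
0.515010410350613,0.482874086366033
0.538902746739055,0.522606169584045
0.663838151361178,0.919225804024718
0.359946529292739,0.2783562630159
0.581769067526407,0.535174498523897
0.954705127930929,1.4908761050192
0.318568116917815,0.259247428714716
0.588670378814022,0.570802458938772
0.409150939699746,0.339317780708685
0.417476519258387,0.33700763375685
0.700342427509312,0.821205550199049
0.445988958509664,0.380537420555793
0.525429022292103,0.546075265049578
0.441308339390401,0.409331758895408
0.47886247440204,0.413910260640849
0.257665037607192,0.148201210522782
0.587923947061425,0.572316722036293
0.742660174216943,0.987308585377318
0.631683993882788,0.742133256236448
0.532255381929614,0.521426101661131
0.633430289253198,0.621718740007817
0.363447158903095,0.254726261141539
0.701216517343453,0.841102544343073
0.425332099542236,0.348502143831624
0.464632020565126,0.410272567123832
0.450332758551647,0.379925904086673
0.509741845149972,0.423587856906095
0.506487706882847,0.439965622808668
0.34847371509414,0.271758998159845
0.494131863743864,0.455325261388744
0.545261734993081,0.492438568293432
0.42416309019026,0.407458627560835
0.527612003228701,0.387418172595405
0.639046051283632,0.697276286501969
0.527029900473339,0.411281766650148
0.781370389154332,1.23549139789405
0.314084855422033,0.224016407453149
0.49968949362325,0.421095039930569
0.574969746425517,0.627498412829868
0.619234652739344,0.716653378086424
0.714569736477123,0.901182224353832
0.442992480141944,0.356442775244532
0.884824329710914,1.55450997142849
0.576045560851913,0.529461351924801
0.544422924110424,0.491998130763485
0.403801520556876,0.31361408963868
0.534032379107171,0.557978810892333
0.500326576119108,0.441321500837952
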