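"time_min","fraction_released","composition","replicate"
0,0,"chi=0.000",1
4,0.0436830972676499,"chi=0.000",1
8,0.0787632202039927,"chi=0.000",1
12,0.119780019530921,"chi=0.000",1
16,0.160393390451347,"chi=0.000",1
20,0.195723099078696,"chi=0.000",1
24,0.223897943265226,"chi=0.000",1
28,0.246811535705507,"chi=0.000",1
32,0.295202976176543,"chi=0.000",1
36,0.300444670826673,"chi=0.000",1
40,0.333391981813929,"chi=0.000",1
44,0.349223586943362,"chi=0.000",1
48,0.370402868850503,"chi=0.000",1
52,0.386335311280977,"chi=0.000",1
56,0.423250090603714,"chi=0.000",1
60,0.450927785161191,"chi=0.000",1
64,0.454369741768055,"chi=0.000",1
68,0.501196465320464,"chi=0.000",1
72,0.499117786592435,"chi=0.000",1
76,0.543390955983297,"chi=0.000",1
80,0.563223928255108,"chi=0.000",1
84,0.583033800579743,"chi=0.000",1
88,0.574161703105766,"chi=0.000",1
92,0.618259582812221,"chi=0.000",1
96,0.610709093344782,"chi=0.000",1
100,0.641893919690281,"chi=0.000",1
104,0.644936762150371,"chi=0.000",1
108,0.653091541988346,"chi=0.000",1
112,0.673467015988385,"chi=0.000",1
116,0.69216902977281,"chi=0.000",1
120,0.70766506722558,"chi=0.000",1
0,0.0223326157552216,"chi=0.200",2
4,0.246270434726505,"chi=0.200",2
8,0.441568614936708,"chi=0.200",2
12,0.570028523355425,"chi=0.200",2
16,0.670502929676221,"chi=0.200",2
20,0.762211820863661,"chi=0.200",2
24,0.819706320211083,"chi=0.200",2
28,0.857958147763994,"chi=0.200",2
32,0.895079231104807,"chi=0.200",2
36,0.904103935358751,"chi=0.200",2
40,0.951616988205232,"chi=0.200",2
44,0.957193476087026,"chi=0.200",2
48,0.976177624077092,"chi=0.200",2
52,0.980419245198657,"chi=0.200",2
56,0.991578705399886,"chi=0.200",2
60,0.993497286317454,"chi=0.200",2
64,0.980120734676017,"chi=0.200",2
68,0.992496611169562,"chi=0.200",2
72,1,"chi=0.200",2
76,0.994928562749305,"chi=0.200",2
80,0.999090422815113,"chi=0.200",2
84,0.976353849027176,"chi=0.200",2
88,0.9966786521081,"chi=0.200",2
92,1,"chi=0.200",2
96,0.997658968252437,"chi=0.200",2
100,1,"chi=0.200",2
104,1,"chi=0.200",2
108,0.992315991890313,"chi=0.200",2
112,0.990453174434508,"chi=0.200",2
116,1,"chi=0.200",2
120,1,"chi=0.200",2
0,0.00163547907444422,"chi=0.375",3
4,0.313696028098926,"chi=0.375",3
8,0.557535920499574,"chi=0.375",3
12,0.694536357525999,"chi=0.375",3
16,0.78482130050611,"chi=0.375",3
20,0.856258998979165,"chi=0.375",3
24,0.9166481214617,"chi=0.375",3
28,0.92718007207726,"chi=0.375",3
32,0.951185074853215,"chi=0.375",3
36,0.979619587281813,"chi=0.375",3
40,0.980648797751848,"chi=0.375",3
44,0.990436035387312,"chi=0.375",3
48,1,"chi=0.375",3
52,0.979208665317517,"chi=0.375",3
56,1,"chi=0.375",3
60,0.990419524978258,"chi=0.375",3
64,0.995927770592674,"chi=0.375",3
68,0.987825279630001,"chi=0.375",3
72,0.988788518956949,"chi=0.375",3
76,1,"chi=0.375",3
80,1,"chi=0.375",3
84,0.986041771753623,"chi=0.375",3
88,0.995012837151135,"chi=0.375",3
92,0.996471851458834,"chi=0.375",3
96,1,"chi=0.375",3
100,0.994753889098703,"chi=0.375",3
104,0.986824698482746,"chi=0.375",3
108,1,"chi=0.375",3
112,0.997734111916179,"chi=0.375",3
116,0.997458114490326,"chi=0.375",3
120,1,"chi=0.375",3
0,0.00430193392484766,"chi=0.600",4
4,0.342938806765097,"chi=0.600",4
8,0.547869905037313,"chi=0.600",4
12,0.729808022946374,"chi=0.600",4
16,0.812813857661399,"chi=0.600",4
20,0.887269204250811,"chi=0.600",4
24,0.91859721030261,"chi=0.600",4
28,0.961161383125653,"chi=0.600",4
32,0.960412621541142,"chi=0.600",4
36,0.98757431009114,"chi=0.600",4
40,0.983686732312498,"chi=0.600",4
44,0.991866298169792,"chi=0.600",4
48,0.988828025908525,"chi=0.600",4
52,0.989202791422456,"chi=0.600",4
56,0.989691627711826,"chi=0.600",4
60,0.988708301158806,"chi=0.600",4
64,1,"chi=0.600",4
68,0.995930660910719,"chi=0.600",4
72,1,"chi=0.600",4
76,0.988231422331556,"chi=0.600",4
80,1,"chi=0.600",4
84,1,"chi=0.600",4
88,1,"chi=0.600",4
92,0.986975175143563,"chi=0.600",4
96,1,"chi=0.600",4
100,0.997264163589017,"chi=0.600",4
104,1,"chi=0.600",4
108,0.999710331803961,"chi=0.600",4
112,0.974216360765671,"chi=0.600",4
116,1,"chi=0.600",4
120,0.993933749439325,"chi=0.600",4
0,0,"chi=0.800",5
4,0.266081066333733,"chi=0.800",5
8,0.475497961835277,"chi=0.800",5
12,0.604119473932831,"chi=0.800",5
16,0.717807950135188,"chi=0.800",5
20,0.782071095402257,"chi=0.800",5
24,0.851737075754015,"chi=0.800",5
28,0.881826207914572,"chi=0.800",5
32,0.895190376815713,"chi=0.800",5
36,0.945635481217233,"chi=0.800",5
40,0.959631195556658,"chi=0.800",5
44,0.974735077218853,"chi=0.800",5
48,0.987063373944736,"chi=0.800",5
52,0.995551127103703,"chi=0.800",5
56,0.993113601181054,"chi=0.800",5
60,1,"chi=0.800",5
64,0.993387344555259,"chi=0.800",5
68,1,"chi=0.800",5
72,0.987370771179141,"chi=0.800",5
76,0.986671412222196,"chi=0.800",5
80,1,"chi=0.800",5
84,1,"chi=0.800",5
88,1,"chi=0.800",5
92,0.997022486382562,"chi=0.800",5
96,0.986907210495479,"chi=0.800",5
100,1,"chi=0.800",5
104,1,"chi=0.800",5
108,0.995468326410374,"chi=0.800",5
112,0.981221778368535,"chi=0.800",5
116,0.997397966734263,"chi=0.800",5
120,1,"chi=0.800",5
0,0.00061351051578296,"chi=1.000",6
4,0.0625350837583078,"chi=1.000",6
8,0.141753021562259,"chi=1.000",6
12,0.210747834129161,"chi=1.000",6
16,0.267402249145486,"chi=1.000",6
20,0.322423098249199,"chi=1.000",6
24,0.367123830244808,"chi=1.000",6
28,0.430780900036931,"chi=1.000",6
32,0.489743997571591,"chi=1.000",6
36,0.533710756303216,"chi=1.000",6
40,0.545075574469963,"chi=1.000",6
44,0.601154505791782,"chi=1.000",6
48,0.620462858963149,"chi=1.000",6
52,0.638357334056227,"chi=1.000",6
56,0.665774663359892,"chi=1.000",6
60,0.687443705808943,"chi=1.000",6
64,0.710840518488486,"chi=1.000",6
68,0.749478395073318,"chi=1.000",6
72,0.782116340941163,"chi=1.000",6
76,0.788323123031242,"chi=1.000",6
80,0.801419696117156,"chi=1.000",6
84,0.818118834868047,"chi=1.000",6
88,0.832875557573636,"chi=1.000",6
92,0.841787361947571,"chi=1.000",6
96,0.876945266689791,"chi=1.000",6
100,0.861677823374958,"chi=1.000",6
104,0.858139643992401,"chi=1.000",6
108,0.87414359732793,"chi=1.000",6
112,0.891351227124857,"chi=1.000",6
116,0.90192365831356,"chi=1.000",6
120,0.913228075330248,"chi=1.000",6
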