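 0.36236044564041103 -0.93199527254569670  0.00892857142857143
-0.89646105524102737  0.44231222224391192  0.02678571428571428
 0.95918734320532606  0.27922509905241438  0.04464285714285714
-0.51816365337213710 -0.85299482901365797  0.06250000000000000
-0.19386325420330883  0.97773195113054379  0.08035714285714286
 0.80210688584110423 -0.58904880762795730  0.09821428571428571
-0.98743224020480713 -0.10726133727258821  0.11607142857142858
 0.65416264280989700  0.74440202478705875  0.13392857142857142
 0.02042390772809782 -0.98820238864915211  0.15178571428571427
-0.68057298829669466  0.71277044595108974  0.16964285714285715
 0.98006909927100538 -0.06563772279810132  0.18750000000000000
-0.76421657344071792 -0.61139305913305786  0.20535714285714285
 0.14991690786798484  0.96317200093667765  0.22321428571428573
 0.53770790924944378 -0.80793240475742922  0.24107142857142858
-0.93776297302240430  0.23142299221585719  0.25892857142857145
 0.84344343267059563  0.46042680661771779  0.27678571428571430
-0.30919241487992299 -0.90420442230472176  0.29464285714285715
-0.38051330198444472  0.87037542302899096  0.31250000000000000
 0.86296656128353089 -0.38229945366131934  0.33035714285714285
-0.88845958844740303 -0.29897553565527935  0.34821428571428570
 0.44986646937028529  0.81462375911827412  0.36607142857142855
 0.21685632619842438 -0.89753673230043274  0.38392857142857145
-0.75985006250112264  0.51107349991264295  0.40178571428571430
 0.89756033240749578  0.13522323076130499  0.41964285714285715
-0.56516704103390514 -0.69941401596549391  0.43750000000000000
-0.05515880430542405  0.88859854757734980  0.45535714285714285
 0.63417295269695584 -0.61146782896857532  0.47321428571428570
-0.87083514462414779  0.02224866126885145  0.49107142857142855
 0.64937740445023473  0.56506698343926420  0.50892857142857140
-0.09591355684759567 -0.84456935821596846  0.52678571428571430
-0.49311299200264991  0.67838317732787268  0.54464285714285710
 0.81021471014700364 -0.16476004813487644  0.56250000000000000
-0.69806160816166918 -0.41939906764970053  0.58035714285714290
 0.22772715007834599  0.76829682641837171  0.59821428571428570
 0.34507999703417019 -0.70807894372368974  0.61607142857142860
-0.71945029539930994  0.28377075038907101  0.63392857142857140
 0.70818862152593653  0.27137475747433676  0.65178571428571430
-0.33186094407537581 -0.66441459772867073  0.66964285714285710
-0.19956751001594106  0.69822386019530813  0.68750000000000000
 0.60402908267807409 -0.37097192386957323  0.70535714285714290
-0.67808278777434372 -0.13101461698203679  0.72321428571428570
 0.40005948965343913  0.53922680060743633  0.74107142857142860
 0.06716222464516962 -0.64770105685424018  0.75892857142857140
-0.47102654857580745  0.41801667983274909  0.77678571428571430
 0.60700155796968147  0.00958322566864890  0.79464285714285710
-0.42358765474073429 -0.40052122134943680  0.81250000000000000
 0.03994761373040678  0.55579780807715362  0.83035714285714290
 0.32885675606735604 -0.41519364096654898  0.84821428571428570
-0.49359148099619937  0.07929521108001020  0.86607142857142860
 0.39054730309874564  0.25718297893628456  0.88392857142857140
-0.10559422594589481 -0.41908517625548541  0.90178571428571430
-0.18650345243961991  0.34564935633416854  0.91964285714285710
 0.32871364194658603 -0.11419759891614008  0.93750000000000000
-0.27128746392072356 -0.11702923357562743  0.95535714285714290
 0.09414294326666187  0.20974045941287250  0.97321428571428570
 0.04190743010081879 -0.12657484257044405  0.99107142857142860
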