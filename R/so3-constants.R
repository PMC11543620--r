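# Frozen SO(3) constants: y<->z involution matrices for the ZYZ Wigner-D
# construction, and real-basis Clebsch-Gordan coupling tensors for all
# triangle-valid (l1, l2, l3) with l <= 2. Derived once by exact linear
# solves against the package's real-spherical-harmonic convention
# (unit-norm, m = -l..l; l=1 ordering (y, z, x)).

.so3_J_0 <- matrix(c(1), 1, 1)
.so3_J_1 <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3)
.so3_J_2 <- matrix(c(0, 0, 0, -1, 0, 0, 1, 0, 0, 0, 0, 0, -0.5, 0, -0.8660254037844386, -1, 0, 0, 0, 0, 0, 0, -0.8660254037844386, 0, 0.5), 5, 5)

.so3_cg <- list(
  `0.0.0` = array(c(1), dim = c(1, 1, 1)),
  `0.1.1` = array(c(0.57735026918962595, -6.3213567138586341e-17, -6.6649632442465268e-17, 4.2515177089665636e-18, 0.57735026918962562, 2.1255325054850971e-17, 1.4693240212902099e-17, -6.393525598355518e-17, 0.57735026918962584), dim = c(1, 3, 3)),
  `0.2.2` = array(c(0.44721359549995815, -1.0042671519062088e-17, -8.111068568130162e-17, 5.3423183540425894e-17, 1.0680412175557714e-16, -4.8838083391816297e-17, 0.44721359549995771, -1.8502388275625637e-17, 1.8236125825670027e-17, -2.2750022804361392e-17, 3.4012559134432101e-17, -5.1581011926297167e-17, 0.44721359549995798, -2.6593748787331568e-17, -2.4345269314816968e-18, 3.4493432522495816e-17, -1.2706768097669055e-19, -2.1389578359401146e-17, 0.44721359549995782, -2.7827509329306076e-17, 5.1292970524319309e-17, 3.6624315565890113e-17, 2.7173705328485999e-17, -4.7381200238498855e-17, 0.44721359549995815), dim = c(1, 5, 5)),
  `1.0.1` = array(c(0.57735026918962573, -1.4711998913337396e-16, -4.1970806178606126e-18, -6.7685081038903799e-17, 0.57735026918962573, 1.1700714508615998e-16, -1.0038364058445767e-16, 4.7075697061721408e-18, 0.57735026918962584), dim = c(3, 1, 3)),
  `1.1.0` = array(c(0.57735026918962595, 1.1377559079297064e-17, 7.1125123477670535e-17, 1.4836113495160436e-17, 0.57735026918962573, -2.3718184381132528e-18, 1.5613972246412702e-17, -1.6293176390288691e-17, 0.57735026918962573), dim = c(3, 3, 1)),
  `1.1.1` = array(c(1.2566061751427416e-17, 1.2942773038489069e-16, -1.2767631872947808e-17, -5.1057357382916962e-17, 9.3662508157924621e-17, 0.40824829046386302, 2.9045789776169974e-17, -0.40824829046386291, -6.75001022534428e-17, -2.6413513056126381e-17, -1.0486228511673002e-16, -0.40824829046386307, -1.4823356449255072e-17, 3.0681257941470914e-17, -4.7680425639848152e-17, 0.40824829046386296, 5.0633375532874525e-18, -2.8721742477930102e-17, 5.1343828051548009e-17, 0.40824829046386285, -6.262498585124957e-17, -0.40824829046386324, 6.3180290691534915e-17, 3.6165860858324444e-17, -6.6577639574071658e-17, -1.9155071235867661e-17, -3.3694463451458212e-18), dim = c(3, 3, 3)),
  `1.1.2` = array(c(-2.491414500777041e-18, 8.9634941814922349e-17, 0.31622776601683766, -2.1558166949917439e-16, -1.820068901961752e-16, 1.2676021903163589e-17, 0.31622776601683805, -1.1536382521779317e-16, 1.1859124285547299e-16, 1.8758473626420698e-16, 0.31622776601683783, -1.103365251735849e-16, 0.31622776601683794, 3.3455746182915411e-17, 7.6870799673733326e-17, -9.6945485073153625e-17, -1.0043194216722378e-16, 8.2065951765035388e-17, -0.18257418583505541, 1.6967763999398149e-16, 7.3075226425523024e-17, 8.3266726846886765e-17, 0.36514837167011094, 2.2204460492503141e-16, 6.245004513516508e-17, 1.3617841228668542e-16, -0.18257418583505544, 1.5765666672508196e-16, 2.6487916967931613e-17, -6.8120556475685644e-17, 2.2027296148482609e-17, 2.4343648483693406e-17, 0.316227766016838, -8.3412530222248627e-17, 0.31622776601683805, -2.3337871862224495e-16, -0.31622776601683783, -8.7420719792270532e-17, -1.7662289157009411e-16, -1.1704581841881232e-16, 1.1904449121417155e-16, 6.0084197747551766e-17, -1.2839993437568953e-16, 8.0750675579498806e-17, 0.31622776601683789), dim = c(3, 3, 5)),
  `1.2.1` = array(c(-4.015818822511702e-17, 1.2774297975725802e-16, 0.31622776601683794, 9.7203483523296015e-17, 0.31622776601683794, 3.1096800773713826e-17, -0.18257418583505541, 1.4701518456787289e-16, -5.2716825639772087e-17, 2.0368524319284276e-17, -4.5347200926149868e-17, 1.4921113330386278e-16, -0.31622776601683822, -3.0229553713766812e-17, -8.247022470889208e-17, 5.9201038507734373e-17, -5.1980717907101903e-17, 2.9639376890322477e-17, 0.31622776601683794, 5.6378512969246231e-17, -5.5511151231257827e-17, -1.1102230246251565e-16, 0.36514837167011077, 2.7755575615628914e-17, 2.8080836267374565e-17, 1.1780419086871542e-16, 0.31622776601683783, 1.2112009562385474e-17, 3.1727762072387132e-17, -6.1732095274729721e-17, 0.31622776601683794, 2.8162497470817556e-19, 2.4021717854978037e-18, -7.7360004043954226e-17, 9.2147777288948024e-18, 3.4886185730981886e-17, 4.9726701949925225e-17, 4.6217458619870815e-17, -0.18257418583505544, 1.161402107400694e-16, 0.31622776601683777, -2.4933387383038807e-17, -3.4139227210677574e-17, 7.1114611664182938e-18, 0.31622776601683777), dim = c(3, 5, 3)),
  `1.2.2` = array(c(-8.6707747943576207e-18, -1.5378888201470848e-17, -2.518511592301518e-16, 0.18257418583505619, 3.2551241555699155e-17, -2.7467774909997668e-16, -2.4040885982698037e-16, 5.7331007954245567e-16, 4.4136977134869365e-16, 4.6005709280203971e-16, -1.7624816453808244e-16, -0.18257418583505464, 1.5412219197800463e-16, 0.36514837167011088, 1.3044967694979951e-16, -0.18257418583505547, -6.326048162688653e-16, -9.8781984851698895e-17, 4.2688602363088688e-16, 4.4354350887379396e-18, 1.791478918607581e-16, -2.6957162359547005e-16, 1.996964876446738e-16, -0.31622776601683766, 6.6830221912006474e-16, 0.18257418583505541, 2.7755575615628907e-17, 0, 0, -0.18257418583505516, -4.1633363423443364e-17, 1.4103301859691438e-15, -2.0198686473404943e-16, 3.6913695841342399e-16, 5.3406507291391376e-16, 0.31622776601683705, -5.6843534057288832e-16, -4.9177832945078208e-17, -5.7085361963729932e-17, -0.31622776601683927, 2.5046954832722788e-16, -4.1948629086411411e-16, 1.0731822738417257e-16, 7.8006652244437523e-17, 1.7370866978996461e-16, -2.0706906241757523e-16, -7.4487060942006447e-16, 0.18257418583505511, -3.3201150433526804e-17, -0.18257418583505503, 9.0903417080653882e-16, 0.31622776601683833, 3.09080204870726e-17, -1.6194846435028592e-17, -1.8288457770757045e-16, 9.6963249603988752e-17, 1.2676271572134229e-17, -0.18257418583505539, 4.987745039577474e-16, 4.2689189992195843e-17, 6.4228263752983361e-16, -0.36514837167011072, -3.9579816746120035e-16, 2.2407578993254707e-16, 2.8696883329912613e-16, 0.18257418583505661, -6.6049088128048568e-16, 3.2405701792760292e-16, 1.995249634728548e-16, 0.18257418583505375, -3.6162631727012011e-16, 1.6057923559104935e-16, 4.6630116658414885e-16, -8.9430585604056259e-17, 4.4669468319581675e-16), dim = c(3, 5, 5)),
  `2.0.2` = array(c(0.44721359549995793, -1.3203913302218587e-16, -3.0930824639615635e-17, -1.1261273242990575e-17, -2.9766523674120891e-17, 2.7959255586427328e-17, 0.44721359549995798, 1.8751354884314293e-17, 6.9763998882370841e-17, 1.2862407609973837e-17, 2.9143581579750921e-17, 4.5699272862449326e-17, 0.44721359549995809, 2.1447353110267312e-17, 6.1104656220653989e-18, -4.0669066126211871e-17, -5.4328433750465389e-17, -5.48804798327122e-17, 0.44721359549995793, -1.7066878580993525e-17, -7.4216456448714479e-18, 3.0411556779115375e-17, -2.5720300173637539e-17, -5.3395114371819739e-17, 0.44721359549995798), dim = c(5, 1, 5)),
  `2.1.1` = array(c(1.174147852970103e-17, -3.129800501948688e-17, 0.18257418583505541, 1.0474074233381468e-16, 0.31622776601683783, -1.0019085535360099e-16, -0.31622776601683816, 4.9929598695057295e-17, -7.8499353408382515e-17, 1.4927632230933883e-16, -0.316227766016838, -1.2371689143232699e-16, 5.3267588015059331e-17, -1.1929746445979106e-17, -1.6537632231540163e-16, 3.9822883438246507e-17, -0.31622776601683789, -1.0301826462743614e-16, 8.2790694330529824e-17, -3.6551165739917568e-17, 2.1337098754514727e-16, 4.163336342344337e-17, -0.36514837167011061, -1.1102230246251565e-16, 2.7755575615628914e-17, 4.5953848531177267e-17, 1.4899513321761922e-16, -4.7738425236594916e-17, -0.31622776601683805, 2.4737757639181385e-17, -0.31622776601683794, 2.1736275155163703e-17, 6.1552215100614443e-17, 3.6375090369636427e-18, 5.2325594078733404e-17, 3.0423055397590729e-17, -5.2587456123569469e-17, -3.9407069386480126e-17, -0.31622776601683805, 7.0557926535281289e-17, -6.9721272515959735e-17, 8.0406181636954671e-17, 0.18257418583505516, -8.7610479259351372e-17, -0.31622776601683827), dim = c(5, 3, 3)),
  `2.1.2` = array(c(-1.2806118670417464e-17, 0.18257418583505552, 2.7595179168391493e-17, 4.6812580849784911e-17, -1.3581594585283523e-17, -9.5224329747836304e-17, 4.0122686660918893e-17, 4.5857530122879269e-17, -5.5504286537703927e-17, 0.36514837167011072, 2.9828255047749217e-17, -5.0642783786353937e-19, 6.7900243996084716e-18, -0.18257418583505564, -1.3186708075961001e-16, -0.18257418583505527, 5.2777030620736305e-18, -7.3062636736599954e-17, -2.255517713129174e-17, 1.2443443390757709e-17, 8.5070483508064798e-17, -5.7018869877370494e-17, -8.6478675782875072e-17, 0.18257418583505539, 3.7296554733501359e-17, -7.285838599102591e-17, 5.5511151231257839e-17, -0.31622776601683783, -0, -0.18257418583505536, 5.0306980803327418e-17, -4.011548038196367e-17, -4.4601366870622451e-17, -0.31622776601683805, -5.5455035298502242e-17, 2.3099859021045658e-17, -8.5727357558660508e-17, 6.0113716508400894e-17, -1.9537661961367695e-17, -2.692633036026696e-17, 1.394470341064755e-17, 0.31622776601683794, 1.8156998257343185e-17, 1.7859689692856926e-17, -8.5737098437553932e-17, 3.0269569403079683e-17, -7.5695099331380565e-18, 0.31622776601683789, -8.5164080648736398e-17, -0.18257418583505544, -8.1966954789325029e-17, -0.18257418583505536, -4.8178387006877361e-17, -7.176063129138434e-18, -5.7743506563746548e-17, 0.1825741858350553, 2.3895222958517446e-17, -1.6822074332470408e-17, -6.9294918381927069e-17, -4.0909573770014578e-18, -1.4535085374883798e-18, 1.025523965064463e-16, -1.2357998942203431e-17, 0.18257418583505552, 4.4201567319518421e-17, -0.36514837167011061, -4.3383968767181208e-17, -6.5972008129848449e-17, -1.025883954067046e-17, -1.0658639091774491e-17, -3.9383643915535955e-17, 0.18257418583505514, -6.7363259745713637e-17, -6.6485310095884555e-17, -6.3712124226573975e-17), dim = c(5, 3, 5)),
  `2.2.0` = array(c(0.44721359549995793, 2.670958581585964e-17, 3.7236899318537786e-17, 5.6329551698868982e-17, 2.4723937942019162e-17, 4.8541176366882254e-17, 0.44721359549995798, 3.5870560667698898e-17, -4.5258718290598363e-17, -1.5962814996893866e-16, 8.8968802625377855e-18, 1.2734983882246021e-18, 0.44721359549995787, 7.9045755267949842e-17, -4.976915317174013e-17, 7.3923177041231182e-17, -7.9855780570072651e-17, 4.767462184027454e-17, 0.44721359549995782, 9.9734961149048326e-17, 2.3110973516119667e-17, -1.0450662769792822e-16, -3.6697847576875422e-17, 5.9860673011597229e-17, 0.44721359549995821), dim = c(5, 5, 1)),
  `2.2.1` = array(c(3.7141921577213564e-18, 0.18257418583505536, -7.6654610701472404e-17, 8.4913989982232614e-17, -7.1570660100844886e-17, -0.1825741858350555, -9.0352296211270612e-17, -1.2347030317238868e-17, 6.3868220614304429e-17, -9.2283246047106528e-17, 1.013941205172047e-16, -3.9487829875200397e-17, -5.3871999762200097e-17, -0.31622776601683783, -2.6448836758604926e-17, -2.0490568650354795e-17, -3.1142138243024094e-18, 0.31622776601683789, 7.100981599298218e-17, -0.18257418583505544, -1.3696522757102033e-18, 1.7276083992198707e-17, -1.400111580493468e-16, 0.18257418583505533, -6.9388939039072271e-17, 9.3675067702747558e-17, 1.6653345369377346e-16, 1.1102230246251563e-16, 0, 0.36514837167011066, -4.8572257327350586e-17, 8.0230960763927316e-17, -8.9717729773175467e-17, 0.18257418583505533, 7.6581519310682163e-17, -6.2450362772520263e-17, 1.6264938411413886e-17, 3.5239958737567905e-17, 2.9113792946551178e-17, -3.2266873092705311e-17, -2.830360593250244e-17, -0.18257418583505539, 4.333462909800362e-17, -1.284398409569058e-17, -4.2714600980613472e-17, -0.36514837167011094, -3.0692662360233194e-17, -7.9071372659136179e-17, 4.3554857664289738e-17, -6.2188417833581871e-17, 6.0698169242006336e-17, -4.6590756096147159e-17, -1.0376788878575618e-17, -0.18257418583505555, -5.4039007968929841e-17, -4.1847927456894713e-17, -7.6293104592142074e-17, -0.31622776601683805, 6.7031011072153113e-17, -0.18257418583505525, -3.0178725119486647e-17, 0.31622776601683805, 1.046480618970718e-16, 3.2918453187380681e-17, 5.316529348383703e-17, 0.18257418583505536, -2.3653183293839517e-17, -8.1111027996124534e-17, -4.5603830363697891e-17, 9.1198555123212798e-17, -9.7213971356376035e-18, 0.18257418583505544, 5.7311308002410016e-17, 8.8112814096365382e-17, 6.9580368485151743e-17), dim = c(5, 5, 3)),
  `2.2.2` = array(c(7.5153506052679448e-19, 7.5450967918831865e-17, 0.23904572186687861, 4.9749843531656063e-17, 1.6385460858248584e-17, 6.9945866328179185e-17, -9.1015409834407063e-17, -5.691568364104051e-18, -0.2070196678027062, -5.0111008454540403e-18, 0.23904572186687859, -5.0959706786044609e-17, 3.6658229804043425e-17, 6.8699041149920083e-19, -7.0579883134273456e-17, 1.7533141082123441e-17, -0.20701966780270631, -2.3500719224490137e-17, 2.2306910450962526e-18, 2.6529194330735354e-17, -5.0269023139378591e-17, 3.8310664929601576e-17, -1.7465819372383681e-18, 3.9811395553899383e-17, 2.6007299612496047e-17, 2.2009304101455746e-17, 2.0816681711721691e-17, -6.245004513516508e-17, -0.20701966780270614, 0, -2.7755575615628926e-17, -8.6736173798840379e-17, -0.11952286093343932, -1.646187357165052e-17, 0.20701966780270648, -4.0975218823426791e-17, -0.11952286093343921, -3.6770229635901224e-17, 1.1137191531149492e-16, -5.9660765639856667e-18, -0.20701966780270639, -2.5762930607213181e-17, -1.5710555347435955e-17, -8.9937958339461641e-18, 2.5147561171032932e-17, -5.3765628085203546e-17, 0.20701966780270625, -6.0024989807176017e-18, -2.5335602485323387e-17, 7.1993141835405655e-17, 0.23904572186687881, -2.3445871979999041e-18, 8.655321468223345e-17, 2.785891363519395e-17, 4.2681143179196952e-17, 1.816123342207946e-17, -0.11952286093343945, 2.8644536693772309e-18, 3.0222559074507076e-17, -4.579187167798837e-17, 3.6081909487138698e-17, 7.4239261453287252e-18, -0.23904572186687864, 2.9784219524302975e-17, -2.1395205214696378e-17, 2.7885171656558834e-17, 5.5764625840723701e-17, 2.7621744409962743e-17, -0.11952286093343951, 4.7195405271588752e-17, -2.1284667415079692e-17, -5.738987030826789e-17, -1.8289135397114859e-17, -4.158762364429165e-17, 0.23904572186687875, 5.0766284418976069e-17, -0.20701966780270625, -5.6200636050322843e-18, -2.3609137580582309e-17, -6.8338618184476974e-18, -0.20701966780270634, -5.1893897030008356e-17, 4.8854742815259923e-18, -7.8456003222955966e-17, 2.3997290428661592e-17, -1.7116841798114907e-17, 1.4542285154935462e-17, 4.1582541446608125e-17, -0.11952286093343931, 1.2095206970317786e-17, -1.9013772083490913e-17, -1.2101983233895821e-17, -0.11952286093343933, 4.5789754095620234e-17, -0.20701966780270636, 3.6466462445192151e-17, 2.559225346834144e-17, -5.5049094758530625e-17, -0.20701966780270634, 3.7154253198362642e-17, -2.9095581738185229e-17, -4.8083519316784886e-17, 1.6285478960384812e-17, -2.9415760192247355e-17, -2.0201735792015069e-17, -3.0652004778765006e-17, 0.20701966780270642, -6.8851073117565826e-18, -1.1284172923321792e-17, -5.8457555338281935e-17, -2.9811324578615113e-17, -1.1108837103240153e-18, 7.0881411092134386e-17, 5.763212173118261e-18, 0.23904572186687881, -5.0601748268971918e-18, -2.174418278896515e-17, 5.5527244857255674e-18, -0.2070196678027062, 4.4697928626609441e-17, -5.36900303946611e-17, -7.5977161302816256e-17, 0.2390457218668787, 4.4169380067522758e-17, 1.0000049799460592e-16), dim = c(5, 5, 5))
)
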