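symbol,process,branch,e1_keV,v1_cm2_g,e2_keV,v2_cm2_g
H,pe,hi,30.000,0.000548343659,100.000,0.00001044195347
H,coh,hi,20.000,0.008403678583,100.000,0.00039484480219
C,pe,hi,30.000,0.058136215212,100.000,0.00117576254216
C,coh,hi,20.000,0.062191198258,100.000,0.00292203838268
N,pe,hi,30.000,0.091886024984,100.000,0.00188083681504
N,coh,hi,20.000,0.078402504665,100.000,0.00368372268662
O,pe,hi,30.000,0.136537219637,100.000,0.00282866485845
O,coh,hi,20.000,0.095843374171,100.000,0.00450317771483
Na,pe,hi,30.000,0.334472373614,100.000,0.00718417751356
Na,coh,hi,20.000,0.147867492140,100.000,0.00694751829341
Mg,pe,hi,30.000,0.445799271168,100.000,0.00969136485902
Mg,coh,hi,20.000,0.173855108074,100.000,0.00816854013186
P,pe,hi,30.000,0.841050890651,100.000,0.01895632855734
P,coh,hi,20.000,0.238320180547,100.000,0.01119741594364
S,pe,hi,30.000,1.046531868871,100.000,0.02387334079976
S,coh,hi,20.000,0.270561753071,100.000,0.01271227841728
Ca,pe,hi,30.000,2.002516195185,100.000,0.04793491115033
Ca,coh,hi,20.000,0.378093241063,100.000,0.01776461932823
Ba,pe,lo,10.000,108.297126081142,37.400,2.91708270049652
Ba,pe,hi,37.400,16.335663122781,120.000,0.66965072689137
Ba,coh,hi,20.000,1.447585087136,100.000,0.06801443460327
Ta,pe,lo,10.000,215.091712838476,67.400,1.59576062183319
Ta,pe,hi,67.400,7.500074922616,120.000,1.70304347064142
Ta,coh,hi,20.000,2.131490143159,100.000,0.10014754796639
Bi,pe,lo,10.000,289.618347590799,90.526,1.25486192994480
Bi,pe,hi,90.526,5.395906298763,120.000,2.68978055217391
Bi,coh,hi,20.000,2.544019709850,100.000,0.11953014971114
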