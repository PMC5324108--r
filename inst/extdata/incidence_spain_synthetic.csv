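sex,age,cum_risk_per100
male,30,0.01
male,35,0.03
male,40,0.08
male,45,0.15
male,50,0.30
male,55,0.60
male,60,1.20
male,65,2.20
male,70,3.80
male,75,6.00
male,80,8.20
male,85,10.00
female,30,0.005
female,35,0.015
female,40,0.04
female,45,0.075
female,50,0.15
female,55,0.30
female,60,0.60
female,65,1.10
female,70,1.90
female,75,3.00
female,80,4.10
female,85,5.00
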