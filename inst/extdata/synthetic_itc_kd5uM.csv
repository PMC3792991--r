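"injection_volume","heat"
2e-06,-0.00026937907
2e-06,-0.00027676928
2e-06,-0.00025433124
2e-06,-0.00026047644
2e-06,-0.00025605035
2e-06,-0.00022475048
2e-06,-0.00018375709
2e-06,-0.00012298257
2e-06,-6.3564722e-05
2e-06,-3.8046482e-05
2e-06,-2.098818e-05
2e-06,-3.7403282e-06
2e-06,-1.2705249e-05
2e-06,-1.2833574e-05
2e-06,1.6694383e-06
2e-06,-1.0273245e-05
2e-06,-8.2930212e-06
2e-06,-6.8863693e-06
2e-06,4.3466889e-06
2e-06,-4.7006286e-06
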