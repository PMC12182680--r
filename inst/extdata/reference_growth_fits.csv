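forest_type,n,model,rmse,r2,aic,mu,k,c,alpha,a,b,d
DBF in north subtropical humid region,66,L,36.9,0.58,488.3,86.59,NA,840000,0.88,-6.14,0.04,91.63
DBF in plateau temperate semi-arid region,24,MM,26.3,0.89,168.9,59.98,357.71,NA,NA,0.093,-170.86,206.63
DBF in tropical humid region,21,MO,12.2,0.74,115.2,205.882,NA,1,0.30,-31.61,-0.05,574.91
DBF in warm/mid-temperate region,132,MM,30.1,0.52,909.1,79.98,228.93,NA,NA,-1.897,0.45,106.18
DNF,159,MM,22.2,0.40,995.3,58.70,167.44,NA,NA,-0.98,0.04,-27.41
EBF in plateau semi-arid region,19,MM,18.0,0.67,118.0,7.27,193.04,NA,NA,-4.51,-0.02,36.09
EBF in tropical humid region,154,MM,26.7,0.57,1021.8,21.43,218.53,NA,NA,0.54,-0.01,10.34
EBF in temperate/subtropical humid/sub-humid region,112,MM,59.1,0.34,923.36,84.95,343.12,NA,NA,2.01,0.04,-54.96
ENF in mid-temperate arid/semi-arid region,68,MM,19.9,0.81,416.7,47.51,406.95,NA,NA,6.36,0.20,-223.52
ENF in mid-temperate sub-humid region,68,MM,32.9,0.71,485.3,3.33,1000.00,NA,NA,2.80,0.19,-941.05
ENF in north subtropical humid region,595,MM,37.9,0.59,4335.4,49.91,442.58,NA,NA,3.38,0.02,-113.53
ENF in plateau temperate semi-arid region,36,MM,29.2,0.84,252.9,44.43,288.43,NA,NA,3.70,0.06,-91.78
ENF in tropical humid region,59,MM,19.1,0.71,357.8,40.63,273.84,NA,NA,6.12,-0.02,-106.07
ENF in warm temperate sub-humid region,109,L,15.3,0.42,607.1,49.54,NA,210000,0.72,0.72,-0.81,-0.01
MF,72,MM,13.0,0.74,348.9,9.48,176.50,NA,NA,1.99,0.01,-90.84
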