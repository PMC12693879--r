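protocol,parameters,Acrylic,Polystyrene,Air,LDPE,PMP,Teflon,Delrin
H,"Hr60 (44.32 mGy), 1 mm",11.38,56.25,467.54,80.92,121.37,372.59,106.23
IE,"UHR Hr72 (5.12 mGy)",3.38,15.21,144.45,22.41,32.16,108.24,29.74
IE,"UHR Hr72 (13.5 mGy)",6.13,35.36,318.26,51.16,76.17,230.28,66.19
IE,"Hr72 (5.04 mGy), 0.4 mm",3.93,29.07,265.10,42.45,62.62,200.78,53.22
IE,"Hr72 (13.3 mGy), 0.4 mm",10.59,44.06,412.75,65.58,100.39,294.66,88.62
TA,"Br40 (2.36 mGy), 1 mm",4.74,35.29,258.53,51.39,72.00,205.56,65.80
TA,"Br40 (3.44 mGy) Flash, 1 mm",5.06,41.12,322.64,60.77,88.84,261.07,73.76
TA,"Br40 (2.36 mGy) Flash, 1 mm",4.25,28.24,220.34,41.14,59.75,163.62,52.30
TA,"UHR Br40 (11.6 mGy)",6.66,39.90,318.37,57.59,84.57,248.73,76.52
TA,"Br40 (11.6 mGy), 0.4 mm",10.62,59.29,457.19,83.97,124.45,360.21,108.81
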