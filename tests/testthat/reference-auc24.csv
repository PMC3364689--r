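# Literature reference 24 h AUC values (mg h/L) for the four metabolism
# scenarios, 1 ppm continuous 24 h inhalation exposure, 37-VOC panel.
# Used as expected values by the simulation-agreement tests.
name,dataset,auc_emin,auc_emax,auc_lmci,auc_umci
benzene,calibration,0.437,0.125,0.155,0.138
bromochloromethane,calibration,0.913,0.229,0.305,0.257
bromodichloromethane,calibration,2.380,0.356,0.523,0.422
carbon tetrachloride,calibration,0.34,0.153,0.224,0.186
chloroethane,calibration,0.156,0.069,0.084,0.076
chloroform,calibration,0.599,0.185,0.257,0.211
dibromomethane,calibration,1.659,0.336,0.466,0.384
"1,1-dichloroethane",calibration,0.391,0.138,0.181,0.158
"1,2-dichloroethane",calibration,1.142,0.205,0.305,0.241
"1,1-dichloroethylene",calibration,0.0698,0.0422,0.0476,0.0447
"cis-1,2-dichloroethylene",calibration,0.702,0.174,0.214,0.188
dichloromethane,calibration,0.65,0.157,0.206,0.174
ethylbenzene,calibration,1.247,0.216,0.32,0.246
hexachloroethane,calibration,3.071,0.494,1.774,0.738
n-hexane,calibration,0.15,0.073,0.129,0.084
isoprene,calibration,0.0459,0.0281,0.084,0.0295
methyl chloride,calibration,0.119,0.054,0.064,0.057
pentachloroethane,calibration,2.584,0.418,0.929,0.595
styrene,calibration,1.497,0.222,0.322,0.246
"1,1,1,2-tetrachloroethane",calibration,1.911,0.337,0.739,0.457
"1,1,2,2-tetrachloroethane",calibration,3.337,0.384,0.717,0.495
toluene,calibration,0.74,0.168,0.223,0.188
"1,1,2-trichloroethane",calibration,1.876,0.284,0.474,0.355
trichloroethylene,calibration,0.721,0.209,0.267,0.227
vinyl chloride,calibration,0.0668,0.0379,0.0425,0.0398
m-xylene,calibration,1.117,0.209,0.308,0.236
bromoform,evaluation,2.122,0.267,0.434,0.328
dibromochloromethane,evaluation,3.114,0.45,0.7,0.527
"trans-1,2-dichloroethylene",evaluation,0.472,0.149,0.185,0.16
ethylene,evaluation,0.00587,0.00408,0.00455,0.00423
furan,evaluation,0.388,0.113,0.131,0.118
halothane,evaluation,0.523,0.22,0.325,0.266
propylene,evaluation,0.0176,0.0116,0.013,0.0121
tetrachloroethylene,evaluation,0.953,0.266,0.363,0.291
"1,1,1-trichloroethane",evaluation,0.271,0.125,0.184,0.15
"1,2,4-trimethylbenzene",evaluation,1.577,0.249,0.425,0.395
o-xylene,evaluation,1.297,0.218,0.325,0.248
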