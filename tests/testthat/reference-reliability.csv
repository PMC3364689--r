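# Published reliability-grid membership for the 37-VOC panel (sensitivity of
# the 24 h AUC to metabolism x uncertainty of the clearance prediction).
# Evaluation-panel uncertainty is uniformly "high" (data-poor convention).
# consistent = FALSE marks the one published cell that contradicts the
# published AUC values themselves (AUC ratio 0.271/0.125 = 2.17 > 2, yet
# classed low-sensitivity); the pipeline reproduces the ratio, not the cell.
name,dataset,sensitivity_class,uncertainty_class,consistent
benzene,calibration,medium,low,TRUE
bromochloromethane,calibration,medium,low,TRUE
bromodichloromethane,calibration,medium,low,TRUE
carbon tetrachloride,calibration,medium,medium,TRUE
chloroethane,calibration,medium,medium,TRUE
chloroform,calibration,medium,low,TRUE
dibromomethane,calibration,medium,low,TRUE
"1,1-dichloroethane",calibration,medium,medium,TRUE
"1,2-dichloroethane",calibration,medium,low,TRUE
"1,1-dichloroethylene",calibration,low,medium,TRUE
"cis-1,2-dichloroethylene",calibration,medium,medium,TRUE
dichloromethane,calibration,medium,medium,TRUE
ethylbenzene,calibration,medium,medium,TRUE
hexachloroethane,calibration,medium,low,TRUE
n-hexane,calibration,medium,low,TRUE
isoprene,calibration,low,low,TRUE
methyl chloride,calibration,medium,medium,TRUE
pentachloroethane,calibration,medium,low,TRUE
styrene,calibration,medium,low,TRUE
"1,1,1,2-tetrachloroethane",calibration,medium,low,TRUE
"1,1,2,2-tetrachloroethane",calibration,medium,low,TRUE
toluene,calibration,medium,low,TRUE
"1,1,2-trichloroethane",calibration,medium,low,TRUE
trichloroethylene,calibration,medium,low,TRUE
vinyl chloride,calibration,low,low,TRUE
m-xylene,calibration,medium,low,TRUE
bromoform,evaluation,medium,high,TRUE
dibromochloromethane,evaluation,medium,high,TRUE
"trans-1,2-dichloroethylene",evaluation,medium,high,TRUE
ethylene,evaluation,low,high,TRUE
furan,evaluation,medium,high,TRUE
halothane,evaluation,medium,high,TRUE
propylene,evaluation,low,high,TRUE
tetrachloroethylene,evaluation,medium,high,TRUE
"1,1,1-trichloroethane",evaluation,low,high,FALSE
"1,2,4-trimethylbenzene",evaluation,medium,high,TRUE
o-xylene,evaluation,medium,high,TRUE
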