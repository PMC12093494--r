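# Extended substrate -> activity -> CAZyme family curation.
# Same families as default_substrate_map() plus additional carbohydrate
# esterase families with reported acetyl xylan esterase activity, as an
# example of extending the shipped map through load_substrate_map().
substrate	activity	ec_number	family
cellulose	endocellulase	3.2.1.4	GH5
cellulose	endocellulase	3.2.1.4	GH6
cellulose	endocellulase	3.2.1.4	GH8
cellulose	endocellulase	3.2.1.4	GH9
cellulose	endocellulase	3.2.1.4	GH10
cellulose	endocellulase	3.2.1.4	GH12
cellulose	endocellulase	3.2.1.4	GH44
cellulose	endocellulase	3.2.1.4	GH45
cellulose	endocellulase	3.2.1.4	GH48
cellulose	endocellulase	3.2.1.4	GH74
cellulose	cellobiohydrolase	3.2.1.91	GH6
cellulose	cellobiohydrolase	3.2.1.91	GH9
cellulose	cellobiohydrolase	3.2.1.91	GH48
cellulose	cellobiohydrolase	3.2.1.91	GH51
cellulose	beta-glucosidase	3.2.1.21	GH1
cellulose	beta-glucosidase	3.2.1.21	GH2
cellulose	beta-glucosidase	3.2.1.21	GH3
cellulose	beta-glucosidase	3.2.1.21	GH30
cellulose	beta-glucosidase	3.2.1.21	GH39
cellulose	beta-glucosidase	3.2.1.21	GH116
xylan	endoxylanase	3.2.1.8	GH5
xylan	endoxylanase	3.2.1.8	GH8
xylan	endoxylanase	3.2.1.8	GH10
xylan	endoxylanase	3.2.1.8	GH30
xylan	endoxylanase	3.2.1.8	GH43
xylan	beta-xylosidase	3.2.1.37	GH1
xylan	beta-xylosidase	3.2.1.37	GH2
xylan	beta-xylosidase	3.2.1.37	GH3
xylan	beta-xylosidase	3.2.1.37	GH39
xylan	beta-xylosidase	3.2.1.37	GH43
xylan	beta-xylosidase	3.2.1.37	GH52
xylan	beta-xylosidase	3.2.1.37	GH116
xylan	alpha-L-arabinofuranosidase	3.2.1.55	GH51
xylan	alpha-glucuronidase	3.2.1.139	GH67
xylan	acetyl xylan esterase	3.1.1.72	CE1
xylan	acetyl xylan esterase	3.1.1.72	CE2
xylan	acetyl xylan esterase	3.1.1.72	CE3
xylan	acetyl xylan esterase	3.1.1.72	CE4
xylan	acetyl xylan esterase	3.1.1.72	CE5
xylan	acetyl xylan esterase	3.1.1.72	CE6
xylan	acetyl xylan esterase	3.1.1.72	CE7
xylan	acetyl xylan esterase	3.1.1.72	CE12
xylan	feruloyl esterase	3.1.1.73	CE1
lignin	laccase	1.10.3.2	AA1
lignin	lignin peroxidase	1.11.1.14	AA2
lignin	manganese peroxidase	1.11.1.13	AA2
starch	alpha-amylase	3.2.1.1	GH13
starch	alpha-amylase	3.2.1.1	GH57
starch	alpha-amylase	3.2.1.1	GH119
starch	beta-amylase	3.2.1.2	GH14
starch	glucoamylase	3.2.1.3	GH15
starch	glucoamylase	3.2.1.3	GH97
chitin	endochitinase	3.2.1.14	GH18
chitin	endochitinase	3.2.1.14	GH19
chitin	endochitinase	3.2.1.14	GH23
chitin	endochitinase	3.2.1.14	GH48
dextran	dextranase	3.2.1.11	GH49
dextran	dextranase	3.2.1.11	GH66
dextran	glucan-1,6-alpha-glucosidase	3.2.1.70	GH13
dextran	glucan-1,6-alpha-glucosidase	3.2.1.70	GH15
dextran	glucan-1,6-alpha-isomaltosidase	3.2.1.94	GH27
fructan	fructan exohydrolase	3.2.1.80	GH32
pectin	pectin methylesterase	3.1.1.11	CE8
pectin	endo-polygalacturonase	3.2.1.15	GH28
pectin	pectin lyase	4.2.2.10	PL1
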