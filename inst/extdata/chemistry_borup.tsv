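# Field geochemistry of the Borup Fiord Pass sulfide spring (BF09-01) and of
# water extracted from the BF09-06b glacial elemental-sulfur deposit, with
# instrument detection limits (DL). pH and temperature from the field record
# (deposit pH carries a +/-0.5 paper-strip uncertainty; deposit temperature
# taken as 0 C, the ice-contact value).
# status: measured | below_detection; value_high holds the upper value where
# two methods bracketed the measurement (spring sulfide) or is blank.
sample	species	value	value_high	unit	detection_limit	uncertainty	status
BF09-01	Total Na	51.562		mM	0.001		measured
BF09-01	Total K	0.303		mM	0.005		measured
BF09-01	Total Mg	12.876		mM	0.0003		measured
BF09-01	Total Ca	17.306		mM	0.003		measured
BF09-01	Total Fe	5		uM	0.215		measured
BF09-01	Fe2+			uM	5		below_detection
BF09-01	NH4+	254		uM	5		measured
BF09-01	Total Mn	1		uM	0.01		measured
BF09-01	Total As	0.217		uM	0.0001		measured
BF09-01	Total Si	88		uM	1.317		measured
BF09-01	Total sulfide	4	6.3	mM	0.005		measured
BF09-01	SO4--	13.029		mM	2		measured
BF09-01	S2O3--	102		uM	2		measured
BF09-01	Cl-	39.072		mM	0.006		measured
BF09-01	F-	54		uM	11		measured
BF09-01	Br-	33		uM	1		measured
BF09-01	NO3-	3		uM	8		measured
BF09-01	NO2-			uM	11		below_detection
BF09-01	PO4---			uM	2		below_detection
BF09-01	alkalinity	15		mg/L	7.5e-4		measured
BF09-01	DOC	3.9		mg/L	0.06		measured
BF09-01	pH	7.37		su		0.14	measured
BF09-01	temperature	-0.3		C			measured
BF09-06b	Total Na	1.601		mM	0.001		measured
BF09-06b	Total K	0.040		mM	0.005		measured
BF09-06b	Total Mg	0.836		mM	0.0003		measured
BF09-06b	Total Ca	10.921		mM	0.003		measured
BF09-06b	Total Fe	1		uM	0.215		measured
BF09-06b	Fe2+			uM	5		below_detection
BF09-06b	NH4+	15		uM	5		measured
BF09-06b	Total Mn	13		uM	0.01		measured
BF09-06b	Total As	0.006		uM	0.0001		measured
BF09-06b	Total Si	22		uM	1.317		measured
BF09-06b	Total sulfide			mM	0.005		below_detection
BF09-06b	SO4--	9.381		mM	2		measured
BF09-06b	S2O3--			uM	2		below_detection
BF09-06b	Cl-	2.119		mM	0.006		measured
BF09-06b	F-	31		uM	11		measured
BF09-06b	Br-			uM	1		below_detection
BF09-06b	NO3-	13		uM	8		measured
BF09-06b	NO2-			uM	11		below_detection
BF09-06b	PO4---			uM	2		below_detection
BF09-06b	alkalinity	163		mg/L	7.5e-4		measured
BF09-06b	DOC	11.4		mg/L	0.06		measured
BF09-06b	pH	6.5		su		0.5	measured
BF09-06b	temperature	0		C			measured
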