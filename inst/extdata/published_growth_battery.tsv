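category	condition	in_vivo	in_silico	gene_knockout	printed_label
luminosity	4 uE fluorescent cool	-	+		TN
luminosity	40 uE fluorescent cool	-	+		FP
luminosity	480 uE fluorescent cool	+	+		TP
luminosity	5 uE fluorescent warm	+	+		TP
luminosity	15 uE fluorescent warm	+	+		TP
luminosity	50 uE fluorescent warm	+	+		TP
luminosity	100 uE fluorescent warm	+	+		TP
luminosity	200 uE fluorescent warm	+	+		TP
luminosity	450 uE white led	+	+		TP
luminosity	1200 uE white led	+	+		TP
luminosity	2100 uE white led	+	+		TP
luminosity	3000 uE white led	-	+		FP
luminosity	red led 673 nm mixotrophic	+	+		TP
luminosity	red led 673 nm autotrophic	+	+		TP
carbon	glucose mixotrophic	+	+		TP
carbon	glucose heterotrophic	+	+		TP
carbon	ethanol heterotrophic	+	+		TP
carbon	ethanol mixotrophic	+	+		TP
carbon	inorganic carbon sources	+	+		FN
other	sodium	+	+		TP
other	nitrite	+	+		TP
other	phosphate	-	-		TP
other	nitrate	+	+		TP
other	ammonium	+	+		TP
other	sulfate	+	+		TP
other	urea levels	+	+		TP
knockout	ammonium	+	+	nitrate reductase	TP
knockout	nitrite	+	+	nitrate reductase	TP
knockout	nitrate	-	-	nitrate reductase	TN
knockout	ammonium	+	+	nitrite reductase	TP
knockout	nitrite	-	-	nitrite reductase	TN
knockout	nitrate	-	-	nitrite reductase	TN
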