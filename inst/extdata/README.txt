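Published validation data for the Nannochloropsis salina genome-scale
metabolic model, transcribed from the printed literature tables.

published_growth_battery.tsv
  32 growth/no-growth observations (in vivo) paired with the published in
  silico calls, spanning light intensities, carbon sources, nitrogen and
  other nutrient conditions, and nitrate/nitrite-reductase knockouts.
  `printed_label` is the TP/TN/FP/FN label exactly as printed; note that
  for two rows it disagrees with the paired call columns (the printed
  counts in the source text are 24 TP, 5 TN, 3 FP, 0 FN). Either way the
  number of exact agreements is 29 of 32.

published_growth_rates.tsv
  Experimental vs predicted specific growth rates (h^-1) for six batch
  conditions (nitrogen source x CO2 level), with the published relative
  error per condition (percent). The printed per-condition errors are not
  exactly reproducible from the rounded printed rates; analyses treat the
  printed error column as the authoritative per-condition value.
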