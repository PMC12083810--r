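# Reference-prior archetypes on the relative-risk scale, one named set per
# treatment contrast. Each entry: label, median RR, SD of the log-RR.
epidex:
  minimally_informative:  {label: "Minimally Informative",   median_rr: 1,   sd_log: 10}
  strongly_enthusiastic:  {label: "Strongly Enthusiastic",   median_rr: 0.6, sd_log: 0.31}
  moderately_enthusiastic: {label: "Moderately Enthusiastic", median_rr: 0.8, sd_log: 0.14}
  moderately_skeptical:   {label: "Moderately Skeptical",    median_rr: 1,   sd_log: 0.31}
  strongly_skeptical:     {label: "Strongly Skeptical",      median_rr: 1,   sd_log: 0.14}
epi:
  minimally_informative:  {label: "Minimally Informative",   median_rr: 1,   sd_log: 10}
  strongly_enthusiastic:  {label: "Strongly Enthusiastic",   median_rr: 0.6, sd_log: 0.31}
  moderately_enthusiastic: {label: "Moderately Enthusiastic", median_rr: 0.8, sd_log: 0.14}
  moderately_skeptical:   {label: "Moderately Skeptical",    median_rr: 1,   sd_log: 0.31}
  strongly_skeptical:     {label: "Strongly Skeptical",      median_rr: 1,   sd_log: 0.14}
dex:
  minimally_informative:  {label: "Minimally Informative",   median_rr: 1,   sd_log: 10}
  strongly_enthusiastic:  {label: "Strongly Enthusiastic",   median_rr: 0.6, sd_log: 0.31}
  moderately_enthusiastic: {label: "Moderately Enthusiastic", median_rr: 0.8, sd_log: 0.14}
  moderately_skeptical:   {label: "Moderately Skeptical",    median_rr: 1,   sd_log: 0.31}
  strongly_skeptical:     {label: "Strongly Skeptical",      median_rr: 1,   sd_log: 0.14}
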