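name,value
faers_total_reports,15656531
duplicate_reports_excluded,2126495
under18_reports_excluded,439205
alk_tki_reports,20064
alk_tki_ild_reports,640
crizotinib_reports,9130
ceritinib_reports,1929
alectinib_reports,4673
brigatinib_reports,2138
lorlatinib_reports,2492
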