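# Hand-built tiny bundles for unit tests.

demo_row <- function(primaryid, caseid = primaryid, caseversion = "1",
                     i_f_code = "I", event_dt = "20200101", age = "60",
                     age_cod = "YR", sex = "M", wt = "70", wt_cod = "KG",
                     reporter_country = "US", occp_cod = "MD") {
  data.table::data.table(
    primaryid = primaryid, caseid = caseid, caseversion = caseversion,
    i_f_code = i_f_code, event_dt = event_dt, age = age,
    age_cod = age_cod, sex = sex, wt = wt, wt_cod = wt_cod,
    reporter_country = reporter_country, occp_cod = occp_cod)
}

drug_row <- function(primaryid, drugname, role_cod = "PS",
                     drug_seq = "1", dose_amt = "500", dose_unit = "MG") {
  data.table::data.table(
    primaryid = primaryid, drug_seq = drug_seq, role_cod = role_cod,
    drugname = drugname, dose_amt = dose_amt, dose_unit = dose_unit)
}

reac_row <- function(primaryid, pt_code, pt_name = pt_code) {
  data.table::data.table(primaryid = primaryid, pt_code = pt_code,
                         pt_name = pt_name)
}

ther_row <- function(primaryid, start_dt, end_dt = NA_character_,
                     dsg_drug_seq = "1") {
  data.table::data.table(primaryid = primaryid,
                         dsg_drug_seq = dsg_drug_seq,
                         start_dt = start_dt, end_dt = end_dt)
}

indi_row <- function(primaryid, indi_drug_seq, indi_pt_code,
                     indi_pt_name = indi_pt_code) {
  data.table::data.table(primaryid = primaryid,
                         indi_drug_seq = indi_drug_seq,
                         indi_pt_code = indi_pt_code,
                         indi_pt_name = indi_pt_name)
}

outc_row <- function(primaryid, outc_cod) {
  data.table::data.table(primaryid = primaryid, outc_cod = outc_cod)
}

rbind_or_null <- function(rows) {
  if (length(rows) == 0) NULL else data.table::rbindlist(rows)
}

# a small but complete bundle: two ALK TKI reports (one ILD case), one
# comparator report
example_bundle <- function() {
  faers_bundle(
    demo = rbind(demo_row("1"), demo_row("2", age = "45", sex = "F"),
                 demo_row("3", age = "70")),
    drug = rbind(drug_row("1", "crizotinib"),
                 drug_row("2", "alectinib"),
                 drug_row("2", "amlodipine", role_cod = "C",
                          drug_seq = "2", dose_amt = NA_character_),
                 drug_row("3", "pembrolizumab")),
    reac = rbind(reac_row("1", "10022611", "Interstitial lung disease"),
                 reac_row("2", "10028813", "Nausea"),
                 reac_row("3", "10028813", "Nausea")),
    ther = rbind(ther_row("1", "20191201"), ther_row("2", "20191215"),
                 ther_row("3", "20191220")),
    indi = indi_row("2", "2", "10020772", "Hypertension"),
    outc = rbind(outc_row("1", "HO"), outc_row("3", "OT")))
}

# fast null synth config for tests that do not need 50k reports
small_null_config <- function(n = 4000, seed = 1, ...) {
  synth_config(
    n_reports = n, duplicate_rate = 0, followup_rate = 0,
    missingness = c(event_dt = 0, age = 0, sex = 0, reporter_country = 0,
                    wt = 0, dose_amt = 0),
    partial_date_rate = 0, pediatric_rate = 0, seed = seed, ...)
}
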