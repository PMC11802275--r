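# Published group summary statistics used as inputs: regional OEF (%) and
# neuropsychological scores for 15 OSA patients vs 16 healthy controls,
# as printed (mean, SD per group, p-value, effect size with its
# interpretation).  Some printed effect sizes are pooled-SD Cohen's d of
# the printed means/SDs; others are consistent with the r-type effect
# size instead (both cutoffs appear in the source's footnotes) -- see
# `es_is_pooled_d`, which marks rows whose printed value matches pooled d
# to +/- 0.01.

#' Published two-group regional OEF and neuropsychological summary table
#'
#' @return data.frame with columns `region`, `block` ("oef_percent" or
#'   "neuropsych"), `mean_a`, `sd_a`, `n_a` (OSA), `mean_b`, `sd_b`, `n_b`
#'   (controls), `p_printed`, `es_printed`, `interpretation_printed`,
#'   `es_is_pooled_d`.
#' @export
osa_oef_summary <- function() {
  oef <- read.csv(text = 'region,mean_a,sd_a,mean_b,sd_b,p_printed,es_printed,interpretation_printed
"Right hemisphere",46.99,6.90,54.20,7.35,0.009,1.010,large
"Left hemisphere",46.85,6.89,54.41,7.51,0.007,1.046,large
"Right cerebral cortex",29.15,4.49,33.64,5.53,0.020,0.886,large
"Left cerebral cortex",29.42,4.49,34.20,5.61,0.014,0.937,large
"Right frontal",40.70,5.91,47.05,7.65,0.016,0.923,large
"Left frontal",42.22,6.74,49.75,6.62,0.004,1.126,large
"Right parietal",41.26,7.51,48.80,8.15,0.012,0.961,large
"Left parietal",41.28,7.35,48.38,7.30,0.012,0.968,large
"Right temporal",48.97,6.36,57.71,8.43,0.003,1.164,large
"Left temporal",47.21,6.58,55.14,8.55,0.007,1.034,large
"Right occipital",54.48,11.10,63.66,7.83,0.012,0.961,large
"Left occipital",51.32,8.55,59.24,9.37,0.020,1.614,large
"Cerebellum",44.15,6.60,48.69,8.45,0.097,0.298,small
"Right cerebellum",44.41,6.72,48.06,9.67,0.235,0.436,small
"Left cerebellum",43.71,6.80,49.09,7.74,0.053,0.347,medium',
    stringsAsFactors = FALSE)
  oef$block <- "oef_percent"
  np <- read.csv(text = 'region,mean_a,sd_a,mean_b,sd_b,p_printed,es_printed,interpretation_printed
"Forward digit span score",7.53,2.77,9.5,2.40,0.055,0.356,medium
"Forward digit span longest train",5.60,1.54,6.35,1.54,0.181,0.248,small
"Backward digit span score",4.86,1.88,7.21,2.15,0.005,0.519,large
"Backward digit span longest train",3.80,1.08,5.28,1.48,0.008,0.493,medium
"Trail making A time (s)",28.47,12.95,22.72,6.07,0.407,0.153,small
"Trail making B time (s)",65.91,23.07,48.49,12.92,0.040,0.380,medium
"Stroop A time (s)",147.96,53.93,111.23,23.21,0.008,0.494,medium
"Stroop A errors",1.26,1.62,0.71,1.97,0.067,0.339,medium
"Stroop B time (s)",109.34,39.57,89.38,14.85,0.116,0.291,small
"Stroop C time (s)",232.91,83.99,182.31,37.97,0.076,0.335,medium
"Stroop C errors",7.60,8.46,2.92,3.27,0.130,0.286,small',
    stringsAsFactors = FALSE)
  np$block <- "neuropsych"
  out <- rbind(oef, np)
  out$n_a <- 15L
  out$n_b <- 16L
  d <- cohens_d_from_summary(out$mean_a, out$sd_a, out$n_a,
                             out$mean_b, out$sd_b, out$n_b)$d
  out$es_is_pooled_d <- abs(d - out$es_printed) <= 0.01
  out[, c("region", "block", "mean_a", "sd_a", "n_a", "mean_b", "sd_b",
          "n_b", "p_printed", "es_printed", "interpretation_printed",
          "es_is_pooled_d")]
}
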