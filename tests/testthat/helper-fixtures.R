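# Shared synthetic fixtures. The quantification sequence keeps G/T bases
# next to the SNP so neither allele channel (A or C) has a neighbouring
# peak bleeding into the integration window.
quant_sequence <- "GTCATTGGTAGTCTTACGT"
quant_snp_index <- 9L
quant_locus <- snp_locus("A", "C", "TTGGT", "GTCTT", label = "test SNP")

design_fractions <- c(0, 0.05, 0.25, 0.40, 0.50, 0.60, 0.75, 0.90, 1.0)

make_quant_trace <- function(fraction, noise_sd = 0, seed = NULL, ...) {
  simulate_trace(
    quant_sequence, quant_snp_index, fraction,
    noise_sd = noise_sd, seed = seed, ...
  )
}

# numeric integral of a Gaussian peak over scan window [lo, hi) — the
# independent oracle for area quantification
gauss_area <- function(amp, center, width, lo, hi) {
  if (is.na(amp) || amp == 0) {
    return(0)
  }
  stats::integrate(
    function(x) amp * exp(-(x - center)^2 / (2 * width^2)),
    lower = lo, upper = hi
  )$value
}
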