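# independent brute-force enumeration: plain loop over the element grid
# (H handled as a vector of all 0:80 values) with the documented
# post-filters, no admissible-range shortcuts
brute_force_formulas <- function(mass, tol_ppm) {
  m <- element_masses()
  H <- 0:80
  out <- character()
  for (C in 0:40) for (N in 0:6) for (O in 0:10) for (S in 0:2) {
    mm <- C * m[["C"]] + H * m[["H"]] + N * m[["N"]] + O * m[["O"]] +
      S * m[["S"]]
    rdbe <- C + 1 + (N - H) / 2
    keep <- abs(mm - mass) / mass * 1e6 <= tol_ppm &
      rdbe >= 0 & rdbe == floor(rdbe) &
      (C <= 1 | H / max(C, 1) <= 3.1)
    for (h in H[keep])
      out <- c(out, breathsig:::.format_formula(C, h, N, O, S))
  }
  sort(out)
}
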