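# Shared helpers: small delimited fixtures written at test time.

write_tmp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Noise-free Michaelis-Menten velocities for one group.
mm_points <- function(vmax, km, s = c(10, 25, 50, 100, 250, 500, 750)) {
  data.frame(substrate_uM = s, velocity = vmax * s / (km + s))
}

# Printed kinetic parameters used throughout: the mefenamic acid table.
bm3 <- function() mefenamic_params("BM3 M11")

MET3 <- "3'-OH-MF"
MET4 <- "4'-OH-MF"
MET5 <- "5-OH-MF"
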