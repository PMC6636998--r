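## Generates the bundled synthetic 25-letter fragment library
## (inst/extdata/alphabet25_synthetic.csv): a deterministic grid of 4-Calpha
## geometries with canonical 0.38 nm virtual bond lengths, spanning 5 virtual
## bond angles x 5 dihedrals. A stand-in for the published 25-letter
## alphabet, whose prototype coordinates are not redistributed here.
## Run from the package root: Rscript data-raw/make_alphabet.R

place4 <- function(theta_deg, phi_deg, b = 0.38) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  p1 <- c(0, 0, 0)
  p2 <- c(b, 0, 0)
  p3 <- p2 + b * c(-cos(th), sin(th), 0)
  # NeRF placement of p4 from (p1, p2, p3) with bond b, angle th, dihedral ph
  bc <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  ab <- p2 - p1
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-b * cos(th), b * sin(th) * cos(ph), b * sin(th) * sin(ph))
  p4 <- p3 + bc * d[1] + m * d[2] + n * d[3]
  rbind(p1, p2, p3, p4)
}

thetas <- c(86, 101, 116, 131, 146)
phis <- c(-144, -72, 0, 72, 144)
grid <- expand.grid(theta = thetas, phi = phis)
protos <- lapply(seq_len(nrow(grid)),
                 function(i) place4(grid$theta[i], grid$phi[i]))
letters25 <- LETTERS[1:25]

rows <- do.call(rbind, lapply(seq_along(protos), function(i) {
  p <- protos[[i]]
  data.frame(letter = letters25[i],
             t(setNames(as.numeric(t(p)),
                        paste0(rep(c("x", "y", "z"), 4), rep(1:4, each = 3)))))
}))
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(format(rows, digits = 10), "inst/extdata/alphabet25_synthetic.csv",
          row.names = FALSE, quote = FALSE)
cat("wrote", nrow(rows), "prototypes\n")
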