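# Brute-force oracles, written independently of the package internals.
#
# The split-drive oracle enumerates every allele fate explicitly (cleave /
# home / resist / restore on each wild-type target copy, then 50:50
# segregation and random union of gametes) and returns offspring class
# probabilities keyed by the package's genotype labels for comparison.

# gamete distribution at the gRNA locus for one parent in a split drive:
# alleles = character(2); homing acts on each "W" copy iff cas9 & grna present
oracle_grna_gametes <- function(alleles, has_cas9, c = 0, h = 0, rho = 0,
                                inframe = 1/3) {
  out <- c(W = 0, G = 0, R = 0, B = 0)
  act <- has_cas9 && any(alleles == "G")
  for (slot in 1:2) {
    a <- alleles[slot]
    if (act && a == "W") {
      out["G"] <- out["G"] + 0.5 * c * h
      out["R"] <- out["R"] + 0.5 * rho * inframe
      out["B"] <- out["B"] + 0.5 * rho * (1 - inframe)
      out["W"] <- out["W"] + 0.5 * (1 - c * h - rho)
    } else {
      out[a] <- out[a] + 0.5
    }
  }
  out
}

# full offspring distribution for a Y-linked-Cas9 split drive cross,
# as a named probability vector over package genotype labels
oracle_split_Y_cross <- function(mother_grna, father_grna, father_cas9,
                                 c = 0, h = 0, rho = 0, inframe = 1/3) {
  egg <- oracle_grna_gametes(mother_grna, FALSE, c, h, rho, inframe)
  sperm <- oracle_grna_gametes(father_grna, father_cas9, c, h, rho, inframe)
  ord <- c("W", "G", "R", "B")
  res <- list()
  add <- function(label, p) res[[label]] <<- (res[[label]] %||% 0) + p
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (ae in names(egg)) for (as_ in names(sperm)) {
    p <- egg[[ae]] * sperm[[as_]]
    if (p == 0) next
    pair <- c(ae, as_)[order(match(c(ae, as_), ord))]
    gl <- paste0(pair[1], "/", pair[2])
    # half daughters (no Y), half sons (father's Y allele)
    add(paste0("F|grna:", gl), p / 2)
    yal <- if (father_cas9) "C" else "W"
    add(paste0("M|cas9:", yal, ";grna:", gl), p / 2)
  }
  unlist(res)
}

# row of an inheritance cube as a named vector over genotype labels
cube_row <- function(arch, mother_label, father_label) {
  fi <- match(mother_label, rownames(arch$cube$scaling))
  mj <- match(father_label, colnames(arch$cube$scaling))
  stopifnot(!is.na(fi), !is.na(mj))
  r <- arch$cube$tau[fi, mj, ]
  stats::setNames(as.numeric(r), dimnames(arch$cube$tau)[[3]])
}

expect_dist_equal <- function(got, want, tol = 1e-12) {
  want <- want[want > 0]
  got_nz <- got[got > tol]
  expect_setequal(names(got_nz), names(want))
  for (nm in names(want)) {
    expect_equal(unname(got[[nm]]), unname(want[[nm]]), tolerance = tol)
  }
}

# small deterministic run helper
tiny_lh <- function(n_eq = 400) life_history_params(n_eq = n_eq)
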