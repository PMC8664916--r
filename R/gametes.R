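## Gamete-level machinery: Mendelian segregation, germline homing, X-shredding,
## and assembly of the offspring-distribution tensor ("inheritance cube").
##
## A gamete is list(type = "X"|"Y", alleles = named character vector): one
## allele per autosomal locus, plus the X-locus allele for X-bearing gametes
## and the Y-locus allele for Y-bearing gametes (where those loci exist).
## Eggs are always X-bearing; offspring sex is decided by the sperm type.

gamete_key <- function(gm) {
  paste0(gm$type, "|", paste(names(gm$alleles), gm$alleles, sep = "=", collapse = ";"))
}

## weighted list of gametes from plain Mendelian segregation of one genotype
mendelian_gametes_raw <- function(g, map) {
  auto <- autosomal_loci(map)
  ## per-autosomal-locus allele options
  opts <- lapply(auto, function(nm) {
    a <- g$alleles[[nm]]
    tab <- table(a) / 2
    list(alleles = names(tab), probs = as.numeric(tab))
  })
  names(opts) <- auto
  ## sex-chromosome options
  if (g$sex == "F") {
    if (!is.na(map$x_locus)) {
      xa <- g$alleles[[map$x_locus]]
      tab <- table(xa) / 2
      sexopts <- lapply(seq_along(tab), function(i)
        list(type = "X", x = names(tab)[i], y = NULL, prob = as.numeric(tab)[i]))
    } else {
      sexopts <- list(list(type = "X", x = NULL, y = NULL, prob = 1))
    }
  } else {
    xall <- if (!is.na(map$x_locus)) g$alleles[[map$x_locus]] else NULL
    yall <- if (!is.na(map$y_locus)) g$alleles[[map$y_locus]] else NULL
    sexopts <- list(list(type = "X", x = xall, y = NULL, prob = 0.5),
                    list(type = "Y", x = NULL, y = yall, prob = 0.5))
  }
  out_g <- list(); out_p <- numeric(0)
  rec <- function(i, acc_alleles, acc_p) {
    if (i > length(auto)) {
      for (so in sexopts) {
        al <- acc_alleles
        if (!is.null(so$x)) al[[map$x_locus]] <- so$x
        if (!is.null(so$y)) al[[map$y_locus]] <- so$y
        out_g[[length(out_g) + 1L]] <<- list(type = so$type, alleles = unlist(al))
        out_p[length(out_p) + 1L] <<- acc_p * so$prob
      }
      return(invisible(NULL))
    }
    nm <- auto[i]
    for (k in seq_along(opts[[nm]]$alleles)) {
      acc <- acc_alleles
      acc[[nm]] <- opts[[nm]]$alleles[k]
      rec(i + 1L, acc, acc_p * opts[[nm]]$probs[k])
    }
  }
  rec(1L, list(), 1)
  list(gametes = out_g, probs = out_p)
}

collapse_gametes <- function(gametes, probs) {
  keys <- vapply(gametes, gamete_key, "")
  keep <- !duplicated(keys)
  agg <- tapply(probs, keys, sum)
  g2 <- gametes[keep]
  k2 <- keys[keep]
  list(gametes = g2, probs = as.numeric(agg[k2]))
}

## Expand a genotype into weighted germline genotypes by applying an allele
## fate distribution independently to every copy of `target` at `locus`.
## fates: named numeric vector over result alleles (must include the identity
## outcome explicitly, e.g. c(G = 0.99, W = 0.01)); sums to 1.
apply_allele_fates <- function(g, map, locus, target, fates) {
  a <- g$alleles[[locus]]
  slots <- which(a == target)
  if (length(slots) == 0L) return(list(genos = list(g), probs = 1))
  genos <- list(); probs <- numeric(0)
  combos <- expand.grid(rep(list(seq_along(fates)), length(slots)))
  for (r in seq_len(nrow(combos))) {
    a2 <- a
    p <- 1
    for (s in seq_along(slots)) {
      k <- combos[r, s]
      a2[slots[s]] <- names(fates)[k]
      p <- p * fates[[k]]
    }
    if (p == 0) next
    g2 <- g
    g2$alleles[[locus]] <- canonical_alleles(a2, map$loci[[locus]])
    genos[[length(genos) + 1L]] <- g2
    probs[length(probs) + 1L] <- p
  }
  list(genos = genos, probs = probs)
}

#' Gamete distribution under Mendelian segregation
#'
#' Exact gamete probabilities for one parental genotype by independent
#' segregation of unlinked loci; co-located sex-chromosome alleles travel with
#' their chromosome. Serves as the null (no drive activity) baseline.
#'
#' @param g A `drive_genotype`.
#' @param map The `locus_map` the genotype belongs to.
#' @return A data.frame with columns `gamete` (key string) and `prob`, summing
#'   to 1, plus the gamete objects in attribute `"gametes"`.
#' @export
#' @examples
#' m <- locus_map(locus("grna", "autosomal", c("W", "G")))
#' g <- genotype("F", list(grna = c("G", "W")), m)
#' mendelian_gamete_dist(g, m)
mendelian_gamete_dist <- function(g, map) {
  raw <- mendelian_gametes_raw(g, map)
  cl <- collapse_gametes(raw$gametes, raw$probs)
  out <- data.frame(gamete = vapply(cl$gametes, gamete_key, ""),
                    prob = cl$probs, stringsAsFactors = FALSE)
  attr(out, "gametes") <- cl$gametes
  out
}

## General gamete distribution with optional germline homing and X-shredding.
## homing: list(locus, target, condition(genotype) -> logical, fates)
## shred:  list(efficiency, resistance, condition(genotype) -> logical)
##         (acts only in males: Xs -> Xr conversion at `resistance` per
##          exposure, then surviving Xs-bearing gametes destroyed with prob
##          `efficiency`; destroyed mass is NOT renormalized away)
gamete_dist <- function(g, map, homing = NULL, shred = NULL) {
  germ <- list(genos = list(g), probs = 1)
  if (!is.null(homing) && isTRUE(homing$condition(g))) {
    germ <- apply_allele_fates(g, map, homing$locus, homing$target, homing$fates)
  }
  shred_on <- !is.null(shred) && g$sex == "M" && isTRUE(shred$condition(g))
  if (shred_on && shred$resistance > 0 && !is.na(map$x_locus)) {
    genos2 <- list(); probs2 <- numeric(0)
    for (i in seq_along(germ$genos)) {
      conv <- apply_allele_fates(germ$genos[[i]], map, map$x_locus, "Xs",
                                 c(Xr = shred$resistance, Xs = 1 - shred$resistance))
      genos2 <- c(genos2, conv$genos)
      probs2 <- c(probs2, germ$probs[i] * conv$probs)
    }
    germ <- list(genos = genos2, probs = probs2)
  }
  all_g <- list(); all_p <- numeric(0)
  for (i in seq_along(germ$genos)) {
    raw <- mendelian_gametes_raw(germ$genos[[i]], map)
    all_g <- c(all_g, raw$gametes)
    all_p <- c(all_p, germ$probs[i] * raw$probs)
  }
  if (shred_on && shred$efficiency > 0 && !is.na(map$x_locus)) {
    for (i in seq_along(all_g)) {
      gm <- all_g[[i]]
      if (gm$type == "X" && identical(unname(gm$alleles[map$x_locus]), "Xs")) {
        all_p[i] <- all_p[i] * (1 - shred$efficiency)
      }
    }
  }
  collapse_gametes(all_g, all_p)
}

## fuse an egg and a sperm into an offspring genotype
fuse_gametes <- function(egg, sperm, map) {
  sex <- if (sperm$type == "Y") "M" else "F"
  al <- list()
  for (nm in autosomal_loci(map)) {
    al[[nm]] <- c(egg$alleles[[nm]], sperm$alleles[[nm]])
  }
  if (!is.na(map$x_locus)) {
    xl <- map$x_locus
    al[[xl]] <- if (sex == "F") c(egg$alleles[[xl]], sperm$alleles[[xl]]) else egg$alleles[[xl]]
  }
  if (!is.na(map$y_locus) && sex == "M") {
    al[[map$y_locus]] <- sperm$alleles[[map$y_locus]]
  }
  genotype(sex, al, map)
}

#' Build an inheritance cube from gamete models
#'
#' Crosses every female genotype with every male genotype, fusing gametes into
#' offspring genotypes. Gamete distributions whose mass is below 1 (X-shredding
#' destroys gametes without renormalization) translate into a per-cross
#' fecundity scaling rather than a renormalized offspring distribution, so
#' fertility reduction emerges mechanically.
#'
#' @param gset A `genotype_set`.
#' @param gamete_fun Function `(genotype) -> list(gametes, probs)`; defaults to
#'   plain Mendelian segregation.
#' @param deposition Optional maternal-carryover model:
#'   `list(d, condition(mother) -> logical, locus, target, fates)` — in zygotes
#'   of qualifying mothers each `target` allele at `locus` is cleaved with
#'   probability `d` and converted per `fates` (probabilities conditional on
#'   cleavage; no homology-directed repair in the soma).
#' @return An `inheritance_cube`: list with `gset`, normalized `tau`
#'   (`[female, male, offspring]`, dimnames by genotype label), and `scaling`
#'   (`[female, male]` realized-fecundity multipliers).
#' @export
build_cube <- function(gset, gamete_fun = NULL, deposition = NULL) {
  map <- gset$map
  if (is.null(gamete_fun)) {
    gamete_fun <- function(g) {
      raw <- mendelian_gametes_raw(g, map)
      collapse_gametes(raw$gametes, raw$probs)
    }
  }
  nG <- nrow(gset$legend)
  fi <- gset$female_idx; mi <- gset$male_idx
  nF <- length(fi); nM <- length(mi)
  eggs <- lapply(gset$genotypes[fi], gamete_fun)
  sperm <- lapply(gset$genotypes[mi], gamete_fun)
  tau <- array(0, dim = c(nF, nM, nG),
               dimnames = list(gset$legend$label[fi], gset$legend$label[mi],
                               gset$legend$label))
  scaling <- matrix(0, nF, nM, dimnames = list(gset$legend$label[fi],
                                               gset$legend$label[mi]))
  ## cache fusion results by (egg key, sperm key)
  fuse_cache <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nF)) {
    for (j in seq_len(nM)) {
      e <- eggs[[i]]; s <- sperm[[j]]
      for (a in seq_along(e$gametes)) {
        for (b in seq_along(s$gametes)) {
          p <- e$probs[a] * s$probs[b]
          if (p == 0) next
          key <- paste(gamete_key(e$gametes[[a]]), gamete_key(s$gametes[[b]]))
          idx <- fuse_cache[[key]]
          if (is.null(idx)) {
            idx <- genotype_index(gset, fuse_gametes(e$gametes[[a]], s$gametes[[b]], map))
            fuse_cache[[key]] <- idx
          }
          tau[i, j, idx] <- tau[i, j, idx] + p
        }
      }
      m <- sum(tau[i, j, ])
      scaling[i, j] <- m
      if (m > 0) tau[i, j, ] <- tau[i, j, ] / m
    }
  }
  cube <- structure(list(gset = gset, tau = tau, scaling = scaling),
                    class = "inheritance_cube")
  if (!is.null(deposition) && deposition$d > 0) {
    cube <- apply_deposition(cube, deposition)
  }
  cube
}

## post-process tensor rows of qualifying mothers: zygotic cleavage from
## maternally deposited nuclease
apply_deposition <- function(cube, deposition) {
  gset <- cube$gset
  map <- gset$map
  nG <- nrow(gset$legend)
  fates <- c(deposition$fates * deposition$d,
             stats::setNames(1 - deposition$d, deposition$target))
  ## genotype -> genotype transition matrix under zygotic conversion
  Tm <- matrix(0, nG, nG)
  for (k in seq_len(nG)) {
    conv <- apply_allele_fates(gset$genotypes[[k]], map, deposition$locus,
                               deposition$target, fates)
    for (q in seq_along(conv$genos)) {
      idx <- genotype_index(gset, conv$genos[[q]])
      Tm[k, idx] <- Tm[k, idx] + conv$probs[q]
    }
  }
  mothers <- which(vapply(gset$genotypes[gset$female_idx], deposition$condition, NA))
  for (i in mothers) {
    for (j in seq_len(ncol(cube$scaling))) {
      cube$tau[i, j, ] <- as.numeric(cube$tau[i, j, ] %*% Tm)
    }
  }
  cube
}

#' @export
print.inheritance_cube <- function(x, ...) {
  d <- dim(x$tau)
  cat("<inheritance_cube> ", d[1], " female x ", d[2], " male -> ",
      d[3], " offspring genotypes\n", sep = "")
  if (any(x$scaling < 1 - 1e-12)) {
    cat("  min fecundity scaling: ", format(min(x$scaling)), "\n", sep = "")
  }
  invisible(x)
}

#' Validate an inheritance cube
#'
#' Report-only structural checks: row-stochasticity, non-negativity, and the
#' sex-linkage constraint that Y-linked alleles reach only male offspring of
#' fathers that carry them.
#'
#' @param cube An `inheritance_cube`.
#' @return List with `ok`, `max_row_deviation`, `min_entry`, and `violations`
#'   (data.frame of offending mother/father/offspring labels, if any).
#' @export
validate_cube <- function(cube) {
  tau <- cube$tau
  gset <- cube$gset
  rs <- apply(tau, c(1, 2), sum)
  max_dev <- max(abs(rs - 1))
  min_entry <- min(tau)
  viol <- list()
  map <- gset$map
  if (!is.na(map$y_locus)) {
    yl <- map$y_locus
    for (al in map$loci[[yl]]$alleles) {
      off_has <- has_allele(gset, yl, al)
      fathers <- gset$genotypes[gset$male_idx]
      dad_has <- vapply(fathers, function(g) any(g$alleles[[yl]] == al), NA)
      bad_j <- which(!dad_has)
      for (j in bad_j) {
        mass <- sum(tau[, j, off_has])
        if (mass > 1e-12) {
          viol[[length(viol) + 1L]] <- data.frame(
            father = gset$legend$label[gset$male_idx[j]],
            allele = al, mass = mass)
        }
      }
    }
  }
  ## female offspring never carry Y alleles (structural, but verify)
  if (!is.na(map$y_locus)) {
    f_with_y <- gset$legend$sex == "F" &
      vapply(gset$genotypes, function(g) !is.null(g$alleles[[map$y_locus]]), NA)
    stopifnot(!any(f_with_y))
  }
  viol <- if (length(viol)) do.call(rbind, viol) else NULL
  bad_rows <- which(abs(rs - 1) > 1e-12, arr.ind = TRUE)
  list(ok = max_dev <= 1e-12 && min_entry >= 0 && is.null(viol),
       max_row_deviation = max_dev,
       min_entry = min_entry,
       bad_rows = if (nrow(bad_rows)) bad_rows else NULL,
       violations = viol)
}
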