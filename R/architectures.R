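#' Germline drive parameters
#'
#' Per-target-allele fates during one germline passage of a drive-carrying
#' heterozygote: a wild-type target allele is converted to the drive allele
#' with probability `cleavage * hdr`, becomes a resistant allele with
#' probability `resistance` (split into in-frame R and out-of-frame B by
#' `inframe`), and otherwise remains wild-type.
#'
#' @param cleavage Cleavage probability per wild-type target allele per
#'   heterozygote germline passage (0-1). Default 0.99, the high-efficiency
#'   regime required for population suppression.
#' @param hdr Fraction of cleaved alleles converted to the drive allele by
#'   homology-directed repair (0-1).
#' @param resistance Probability that a target allele becomes resistant per
#'   heterozygote passage (0-1). Default 1e-6, the low-resistance regime.
#' @param inframe Fraction of resistant alleles that are in-frame/functional
#'   (R); the remainder are out-of-frame/costly (B). Default 1/3, the standard
#'   reading-frame convention for end-joining repair.
#' @param deposition Probability of zygotic target cleavage from maternally
#'   deposited nuclease (0-1); default 0.
#' @return A `drive_params` list.
#' @export
drive_params <- function(cleavage = 0.99, hdr = 1, resistance = 1e-6,
                         inframe = 1/3, deposition = 0) {
  p <- list(cleavage = cleavage, hdr = hdr, resistance = resistance,
            inframe = inframe, deposition = deposition)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("drive_params$", nm, " must be a single probability in [0,1]")
  }
  if (cleavage * hdr + resistance > 1)
    stop("cleavage*hdr + resistance must not exceed 1 (allele fates must partition)")
  structure(p, class = "drive_params")
}

## allele fate vector for one wild-type target allele in a drive germline
drive_fates <- function(p, drive_allele) {
  f <- c(p$cleavage * p$hdr,
         p$resistance * p$inframe,
         p$resistance * (1 - p$inframe))
  f <- c(f, 1 - sum(f))
  names(f) <- c(drive_allele, "R", "B", "W")
  f[f > 0 | names(f) == "W"]
}

#' X-shredder parameters
#'
#' @param efficiency Probability that a shred-susceptible X-bearing gamete of a
#'   shredder-carrying male is destroyed (0-1).
#' @param resistance Probability that an X target converts to the
#'   shred-resistant allele Xr per germline exposure (0-1). Default 1e-6.
#' @param fertility_cost Fertility model for shredder-sired crosses. `NULL`
#'   (default): realized fecundity is proportional to the surviving-gamete
#'   mass, i.e. gamete destruction translates one-for-one into zygote loss.
#'   A number in \[0, 1\]: sperm are treated as in excess (the usual situation
#'   in mosquitoes), the offspring distribution is carried by surviving
#'   gametes, and crosses sired by shredder males produce
#'   `1 - fertility_cost` times the normal egg output.
#' @return A `shredder_params` list.
#' @export
shredder_params <- function(efficiency = 0.95, resistance = 1e-6,
                            fertility_cost = NULL) {
  stopifnot(is.numeric(efficiency), length(efficiency) == 1L,
            efficiency >= 0, efficiency <= 1,
            is.numeric(resistance), length(resistance) == 1L,
            resistance >= 0, resistance <= 1)
  if (!is.null(fertility_cost)) {
    stopifnot(is.numeric(fertility_cost), length(fertility_cost) == 1L,
              fertility_cost >= 0, fertility_cost <= 1)
  }
  structure(list(efficiency = efficiency, resistance = resistance,
                 fertility_cost = fertility_cost),
            class = "shredder_params")
}

#' Fitness cost parameters
#'
#' Costs are dominant (expressed with one or more copies) and additive across
#' distinct cost-bearing allele classes: the fitness multiplier of a genotype
#' is `1 - sum(costs of classes present)`, floored at `floor`. Which
#' life-history channels a cost hits (female fecundity, adult longevity) is
#' decided by the architecture builder.
#'
#' @param cost_cas9 Selection coefficient of carrying the nuclease construct.
#' @param cost_effector Selection coefficient of the gRNA/effector construct.
#' @param cost_B Selection coefficient of an out-of-frame resistant allele.
#' @param floor Minimum multiplier (guards against negative rates).
#' @return A `fitness_params` list.
#' @export
fitness_params <- function(cost_cas9 = 0.1, cost_effector = 0.05,
                           cost_B = 0.1, floor = 0.05) {
  p <- list(cost_cas9 = cost_cas9, cost_effector = cost_effector,
            cost_B = cost_B, floor = floor)
  for (nm in c("cost_cas9", "cost_effector", "cost_B")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("fitness_params$", nm, " must be in [0,1]")
  }
  stopifnot(floor > 0, floor <= 1)
  structure(p, class = "fitness_params")
}

fitness_multiplier <- function(costs_present, fitness) {
  max(1 - sum(costs_present), fitness$floor)
}

new_architecture <- function(name, gset, cube, traits, params,
                             wild_female, wild_male, release_label,
                             effector) {
  stopifnot(all(c("fecundity", "mortality_mult", "fertile", "eta") %in% names(traits)))
  structure(list(name = name, map = gset$map, gset = gset, cube = cube,
                 traits = traits, params = params,
                 wild_female = wild_female, wild_male = wild_male,
                 release_label = release_label, effector = effector),
            class = "drive_architecture")
}

#' @export
print.drive_architecture <- function(x, ...) {
  cat("<drive_architecture> ", x$name, ": ", nrow(x$gset$legend),
      " genotypes; release genotype ", x$release_label, "\n", sep = "")
  invisible(x)
}

base_traits <- function(gset) {
  data.frame(id = gset$legend$id, label = gset$legend$label,
             sex = gset$legend$sex,
             fecundity = 1, mortality_mult = 1, fertile = TRUE, eta = 1,
             stringsAsFactors = FALSE)
}

#' Split drive architecture (Cas9 and gRNA/effector at separate loci)
#'
#' The gRNA/effector allele G sits at an autosomal locus with alleles
#' \{W, G, R, B\}; the Cas9 allele C sits at a second locus that is Y-linked,
#' X-linked or autosomal. Germline homing (W -> G) occurs only in individuals
#' carrying at least one Cas9 allele, at least one gRNA allele and a wild-type
#' target allele; everyone else segregates Mendelianly. For Y-linked Cas9,
#' homing can occur only in males by construction.
#'
#' Fitness costs (Cas9, effector, B; dominant, additive) are applied to both
#' female fecundity and adult longevity.
#'
#' @param linkage Cas9 linkage: `"Y"`, `"X"` or `"autosomal"`.
#' @param drive A `drive_params`.
#' @param fitness A `fitness_params`.
#' @return A `drive_architecture`.
#' @export
split_drive_architecture <- function(linkage = c("Y", "X", "autosomal"),
                                     drive = drive_params(),
                                     fitness = fitness_params()) {
  linkage <- match.arg(linkage)
  map <- locus_map(
    locus("cas9", linkage, c("W", "C")),
    locus("grna", "autosomal", c("W", "G", "R", "B"))
  )
  gset <- enumerate_genotypes(map)
  has_c <- has_allele(gset, "cas9", "C")
  has_g <- has_allele(gset, "grna", "G")
  homing <- list(
    locus = "grna", target = "W",
    condition = function(g) any(g$alleles$cas9 == "C") && any(g$alleles$grna == "G"),
    fates = drive_fates(drive, "G"))
  deposition <- NULL
  if (drive$deposition > 0) {
    deposition <- list(
      d = drive$deposition, locus = "grna", target = "W",
      condition = function(g) any(g$alleles$cas9 == "C") && any(g$alleles$grna == "G"),
      fates = c(R = drive$inframe, B = 1 - drive$inframe))
  }
  cube <- build_cube(gset,
                     gamete_fun = function(g) gamete_dist(g, map, homing = homing),
                     deposition = deposition)
  tr <- base_traits(gset)
  has_b <- has_allele(gset, "grna", "B")
  for (k in seq_len(nrow(tr))) {
    costs <- c(if (has_c[k]) fitness$cost_cas9,
               if (has_g[k]) fitness$cost_effector,
               if (has_b[k]) fitness$cost_B)
    mult <- fitness_multiplier(costs, fitness)
    tr$mortality_mult[k] <- 1 / mult
    if (tr$sex[k] == "F") tr$fecundity[k] <- mult
  }
  rel <- switch(linkage,
    Y = genotype("M", list(cas9 = "C", grna = c("G", "G")), map),
    X = genotype("M", list(cas9 = "C", grna = c("G", "G")), map),
    autosomal = genotype("M", list(cas9 = c("C", "C"), grna = c("G", "G")), map))
  wf <- genotype("F", list(cas9 = if (linkage == "Y") NULL else c("W", "W")[seq_len(slots_for(map$loci$cas9, "F"))],
                           grna = c("W", "W")), map)
  wm <- genotype("M", list(cas9 = rep("W", slots_for(map$loci$cas9, "M")),
                           grna = c("W", "W")), map)
  new_architecture(paste0("split_drive_", linkage), gset, cube, tr,
                   list(drive = drive, fitness = fitness, linkage = linkage),
                   genotype_label(wf), genotype_label(wm), genotype_label(rel),
                   effector = list(locus = "grna", allele = "G"))
}

#' X-shredder architecture (sex-ratio distorter)
#'
#' A shredder construct S (Cas9 + X-targeting gRNAs) sits on the Y chromosome
#' or on an autosome; the X chromosome carries shred-susceptible (Xs) or
#' shred-resistant (Xr) target states. In shredder-carrying males each
#' Xs-bearing gamete is destroyed with probability `efficiency`; destroyed
#' gametes are not renormalized away, so the realized fecundity of the cross is
#' scaled by the surviving-gamete fraction and a male-biased sex ratio and a
#' fertility reduction emerge mechanically. Xs converts to Xr at rate
#' `resistance` per exposure. A Y-linked shredder passes to all sons.
#'
#' Construct fitness costs are applied to adult longevity only (the fecundity
#' effect is the mechanical gamete loss).
#'
#' @param linkage `"Y"` or `"autosomal"` (an X-linked X-shredder is
#'   self-destructive and unsupported).
#' @param shred A `shredder_params`.
#' @param fitness A `fitness_params` (only `cost_cas9` is used).
#' @return A `drive_architecture`.
#' @export
x_shredder_architecture <- function(linkage = c("Y", "autosomal"),
                                    shred = shredder_params(),
                                    fitness = fitness_params()) {
  linkage <- tryCatch(match.arg(linkage), error = function(e)
    stop("unsupported X-shredder linkage (must be Y or autosomal)"))
  map <- if (linkage == "Y") {
    locus_map(locus("shredder", "Y", c("W", "S")),
              locus("xchrom", "X", c("Xs", "Xr")))
  } else {
    locus_map(locus("shredder", "autosomal", c("W", "S")),
              locus("xchrom", "X", c("Xs", "Xr")))
  }
  gset <- enumerate_genotypes(map)
  shred_model <- list(efficiency = shred$efficiency, resistance = shred$resistance,
                      condition = function(g) any(g$alleles$shredder == "S"))
  cube <- build_cube(gset, gamete_fun = function(g)
    gamete_dist(g, map, shred = shred_model))
  if (!is.null(shred$fertility_cost)) {
    ## sperm-excess model: the sex-ratio bias of surviving gametes stands, but
    ## zygote production drops only by the stated fertility cost
    shred_dads <- vapply(gset$genotypes[gset$male_idx],
                         function(g) any(g$alleles$shredder == "S"), NA)
    cube$scaling[, shred_dads] <- 1 - shred$fertility_cost
    cube$scaling[, !shred_dads] <- 1
  }
  tr <- base_traits(gset)
  has_s <- has_allele(gset, "shredder", "S")
  for (k in seq_len(nrow(tr))) {
    costs <- c(if (has_s[k]) fitness$cost_cas9)
    tr$mortality_mult[k] <- 1 / fitness_multiplier(costs, fitness)
  }
  rel <- if (linkage == "Y") {
    genotype("M", list(shredder = "S", xchrom = "Xs"), map)
  } else {
    genotype("M", list(shredder = c("S", "S"), xchrom = "Xs"), map)
  }
  wf <- genotype("F", list(shredder = if (linkage == "Y") NULL else c("W", "W"),
                           xchrom = c("Xs", "Xs")), map)
  wm <- genotype("M", list(shredder = if (linkage == "Y") "W" else c("W", "W"),
                           xchrom = "Xs"), map)
  new_architecture(paste0("x_shredder_", linkage), gset, cube, tr,
                   list(shred = shred, fitness = fitness, linkage = linkage),
                   genotype_label(wf), genotype_label(wm), genotype_label(rel),
                   effector = list(locus = "shredder", allele = "S"))
}

#' Homing suppression drive architecture
#'
#' A single autosomal locus with alleles \{W, H, R, B\} where H is an
#' autonomous homing construct inserted in a gene required for female
#' fertility. Homing (W -> H) occurs in H/W germlines of both sexes. Females
#' whose two alleles are both drawn from \{H, B\} (H/H, H/B, B/B) lack a
#' functional copy of the fertility gene and are infertile; R restores
#' function. Construct and B costs are applied to adult longevity only.
#'
#' Heterozygous (H/W, H/R) females additionally suffer a somatic fertility
#' cost: leaky somatic expression of the nuclease mosaically disrupts the
#' fertility target in the carrier herself, reducing her fecundity — the
#' characteristic drag on fertility-gene homing drives.
#'
#' @param drive A `drive_params`.
#' @param fitness A `fitness_params` (`cost_cas9` for H, `cost_B` for B).
#' @param somatic_cost Fractional fecundity reduction of fertile H-carrier
#'   females from leaky somatic target disruption (0-1).
#' @return A `drive_architecture`.
#' @export
homing_suppression_architecture <- function(drive = drive_params(),
                                            fitness = fitness_params(),
                                            somatic_cost = 0.5) {
  stopifnot(is.numeric(somatic_cost), length(somatic_cost) == 1L,
            somatic_cost >= 0, somatic_cost <= 1)
  map <- locus_map(locus("drive", "autosomal", c("W", "H", "R", "B")))
  gset <- enumerate_genotypes(map)
  homing <- list(
    locus = "drive", target = "W",
    condition = function(g) any(g$alleles$drive == "H"),
    fates = drive_fates(drive, "H"))
  deposition <- NULL
  if (drive$deposition > 0) {
    deposition <- list(
      d = drive$deposition, locus = "drive", target = "W",
      condition = function(g) any(g$alleles$drive == "H"),
      fates = c(R = drive$inframe, B = 1 - drive$inframe))
  }
  cube <- build_cube(gset, gamete_fun = function(g)
    gamete_dist(g, map, homing = homing), deposition = deposition)
  tr <- base_traits(gset)
  has_h <- has_allele(gset, "drive", "H")
  has_b <- has_allele(gset, "drive", "B")
  nH <- allele_count(gset, "drive", "H")
  nB <- allele_count(gset, "drive", "B")
  for (k in seq_len(nrow(tr))) {
    costs <- c(if (has_h[k]) fitness$cost_cas9,
               if (has_b[k]) fitness$cost_B)
    tr$mortality_mult[k] <- 1 / fitness_multiplier(costs, fitness)
    if (tr$sex[k] == "F" && (nH[k] + nB[k]) == 2L) tr$fertile[k] <- FALSE
    if (tr$sex[k] == "F" && tr$fertile[k] && has_h[k])
      tr$fecundity[k] <- 1 - somatic_cost
  }
  rel <- genotype("M", list(drive = c("H", "H")), map)
  wf <- genotype("F", list(drive = c("W", "W")), map)
  wm <- genotype("M", list(drive = c("W", "W")), map)
  new_architecture("homing_suppression", gset, cube, tr,
                   list(drive = drive, fitness = fitness),
                   genotype_label(wf), genotype_label(wm), genotype_label(rel),
                   effector = list(locus = "drive", allele = "H"))
}

#' Mendelian (drive-free) architecture over an arbitrary locus map
#'
#' Useful as the null model: the same genotype bookkeeping with plain
#' segregation and neutral traits.
#'
#' @param map A `locus_map`.
#' @return A `drive_architecture`.
#' @export
mendelian_architecture <- function(map) {
  gset <- enumerate_genotypes(map)
  cube <- build_cube(gset)
  tr <- base_traits(gset)
  first_al <- lapply(map$loci, function(lc) lc$alleles[1L])
  wf_al <- list(); wm_al <- list()
  for (nm in locus_names(map)) {
    lc <- map$loci[[nm]]
    nf <- slots_for(lc, "F"); nm2 <- slots_for(lc, "M")
    if (nf > 0) wf_al[[nm]] <- rep(first_al[[nm]], nf)
    if (nm2 > 0) wm_al[[nm]] <- rep(first_al[[nm]], nm2)
  }
  wf <- genotype("F", wf_al, map)
  wm <- genotype("M", wm_al, map)
  new_architecture("mendelian", gset, cube, tr, list(),
                   genotype_label(wf), genotype_label(wm), genotype_label(wm),
                   effector = NULL)
}
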