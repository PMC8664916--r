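#' Define a genetic locus
#'
#' A locus is a named slot in the genome with a fixed allele set and a
#' linkage class. Autosomal loci carry two allele copies in both sexes;
#' X-linked loci carry two copies in females and one in males; Y-linked loci
#' carry one copy in males and none in females.
#'
#' @param name Character scalar, locus name (e.g. `"cas9"`, `"grna"`).
#' @param linkage One of `"autosomal"`, `"X"`, `"Y"`.
#' @param alleles Character vector of allele symbols; the order given here is
#'   the canonical sort order used when genotypes are enumerated.
#' @return A `drive_locus` object.
#' @export
#' @examples
#' locus("grna", "autosomal", c("W", "G", "R", "B"))
locus <- function(name, linkage = c("autosomal", "X", "Y"), alleles) {
  linkage <- match.arg(linkage)
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  stopifnot(is.character(alleles), length(alleles) >= 1L, !anyDuplicated(alleles))
  structure(list(name = name, linkage = linkage, alleles = alleles),
            class = "drive_locus")
}

#' Assemble a locus map
#'
#' A locus map is an ordered collection of loci describing one drive
#' architecture's genome. At most one X-linked and one Y-linked locus are
#' allowed (they stand for the sex chromosome pair); sex is always tracked
#' even when neither sex chromosome carries an explicit allele set.
#'
#' @param ... `drive_locus` objects.
#' @return A `locus_map` object.
#' @export
locus_map <- function(...) {
  loci <- list(...)
  if (length(loci) == 1L && is.list(loci[[1L]]) && !inherits(loci[[1L]], "drive_locus")) {
    loci <- loci[[1L]]
  }
  stopifnot(length(loci) >= 1L)
  for (lc in loci) {
    if (!inherits(lc, "drive_locus")) stop("all arguments must be drive_locus objects")
  }
  nms <- vapply(loci, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate locus names: ", paste(nms[duplicated(nms)], collapse = ", "))
  linkages <- vapply(loci, `[[`, "", "linkage")
  if (sum(linkages == "X") > 1L) stop("at most one X-linked locus is supported")
  if (sum(linkages == "Y") > 1L) stop("at most one Y-linked locus is supported")
  names(loci) <- nms
  structure(list(loci = loci,
                 x_locus = if (any(linkages == "X")) nms[linkages == "X"] else NA_character_,
                 y_locus = if (any(linkages == "Y")) nms[linkages == "Y"] else NA_character_),
            class = "locus_map")
}

locus_names <- function(map) names(map$loci)

autosomal_loci <- function(map) {
  names(map$loci)[vapply(map$loci, function(l) l$linkage == "autosomal", NA)]
}

#' @export
print.locus_map <- function(x, ...) {
  cat("<locus_map> ", length(x$loci), " loci\n", sep = "")
  for (lc in x$loci) {
    cat(sprintf("  %-10s %-9s {%s}\n", lc$name, lc$linkage,
                paste(lc$alleles, collapse = ", ")))
  }
  invisible(x)
}

## ---- genotypes --------------------------------------------------------------

## A genotype is list(sex = "F"|"M", alleles = named list of character vectors).
## Allele vectors are kept in canonical order (sorted by position in the locus
## allele set) so enumeration, labels and tensor indices are reproducible.

canonical_alleles <- function(alleles, lc) {
  idx <- match(alleles, lc$alleles)
  if (anyNA(idx)) stop("unknown allele(s) for locus '", lc$name, "': ",
                       paste(alleles[is.na(idx)], collapse = ", "))
  alleles[order(idx)]
}

slots_for <- function(lc, sex) {
  switch(lc$linkage,
         autosomal = 2L,
         X = if (sex == "F") 2L else 1L,
         Y = if (sex == "F") 0L else 1L)
}

#' Construct a genotype
#'
#' @param sex `"F"` or `"M"`.
#' @param alleles Named list, one entry per applicable locus, each a character
#'   vector with the sex-appropriate copy number (2 for autosomal; X: 2 in
#'   females, 1 in males; Y: 1 in males, absent in females).
#' @param map A `locus_map`.
#' @return A canonical `drive_genotype` object.
#' @export
genotype <- function(sex, alleles, map) {
  stopifnot(sex %in% c("F", "M"))
  out <- list()
  for (nm in locus_names(map)) {
    lc <- map$loci[[nm]]
    ns <- slots_for(lc, sex)
    got <- alleles[[nm]]
    if (ns == 0L) {
      if (!is.null(got) && length(got) > 0L)
        stop("Y-linked locus '", nm, "' cannot carry alleles in a female")
      next
    }
    if (is.null(got) || length(got) != ns)
      stop("locus '", nm, "' requires ", ns, " allele(s) for sex ", sex)
    out[[nm]] <- canonical_alleles(got, lc)
  }
  structure(list(sex = sex, alleles = out), class = "drive_genotype")
}

genotype_label <- function(g) {
  parts <- vapply(names(g$alleles), function(nm) {
    paste0(nm, ":", paste(g$alleles[[nm]], collapse = "/"))
  }, "")
  paste0(g$sex, "|", paste(parts, collapse = ";"))
}

#' @export
print.drive_genotype <- function(x, ...) {
  cat("<genotype> ", genotype_label(x), "\n", sep = "")
  invisible(x)
}

unordered_pairs <- function(alleles) {
  n <- length(alleles)
  out <- list()
  for (i in seq_len(n)) for (j in i:n) out[[length(out) + 1L]] <- c(alleles[i], alleles[j])
  out
}

#' Enumerate all genotypes of a locus map
#'
#' Enumeration is deterministic: sexes in order F, M; within each sex the
#' cartesian product over loci in map order, allele pairs in canonical order.
#'
#' @param map A `locus_map`.
#' @return A `genotype_set`: list with `genotypes` (list of `drive_genotype`),
#'   `legend` (data.frame of id, sex, label), and index vectors `female_idx`,
#'   `male_idx`.
#' @export
enumerate_genotypes <- function(map) {
  genos <- list()
  for (sex in c("F", "M")) {
    opts <- list()
    for (nm in locus_names(map)) {
      lc <- map$loci[[nm]]
      ns <- slots_for(lc, sex)
      if (ns == 0L) next
      opts[[nm]] <- if (ns == 2L) unordered_pairs(lc$alleles) else as.list(lc$alleles)
    }
    grid <- list(list())
    for (nm in names(opts)) {
      grid <- unlist(lapply(grid, function(partial) {
        lapply(opts[[nm]], function(a) c(partial, stats::setNames(list(a), nm)))
      }), recursive = FALSE)
    }
    for (al in grid) genos[[length(genos) + 1L]] <- genotype(sex, al, map)
  }
  labels <- vapply(genos, genotype_label, "")
  sexes <- vapply(genos, `[[`, "", "sex")
  legend <- data.frame(id = seq_along(genos), sex = sexes, label = labels,
                       stringsAsFactors = FALSE)
  structure(list(map = map, genotypes = genos, legend = legend,
                 female_idx = which(sexes == "F"), male_idx = which(sexes == "M")),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("<genotype_set> ", nrow(x$legend), " genotypes (",
      length(x$female_idx), " F, ", length(x$male_idx), " M)\n", sep = "")
  invisible(x)
}

genotype_index <- function(gset, g) {
  i <- match(genotype_label(g), gset$legend$label)
  if (is.na(i)) stop("genotype not in set: ", genotype_label(g))
  i
}

#' Test which genotypes carry an allele
#'
#' @param gset A `genotype_set`.
#' @param locus Locus name.
#' @param allele Allele symbol.
#' @param min_copies Minimum copy number (default 1).
#' @return Logical vector over genotype ids.
#' @export
has_allele <- function(gset, locus, allele, min_copies = 1L) {
  vapply(gset$genotypes, function(g) {
    a <- g$alleles[[locus]]
    !is.null(a) && sum(a == allele) >= min_copies
  }, NA)
}

allele_count <- function(gset, locus, allele) {
  vapply(gset$genotypes, function(g) sum(g$alleles[[locus]] == allele), 0L)
}
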