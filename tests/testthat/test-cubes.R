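all_archs <- function() {
  list(
    split_Y = split_drive_architecture("Y"),
    split_X = split_drive_architecture("X"),
    split_A = split_drive_architecture("autosomal"),
    shred_Y = x_shredder_architecture("Y"),
    shred_A = x_shredder_architecture("autosomal"),
    homing = homing_suppression_architecture()
  )
}

test_that("every built-in cube is row-stochastic, non-negative and sex-consistent", {
  for (arch in all_archs()) {
    v <- validate_cube(arch$cube)
    expect_true(v$ok, label = paste(arch$name, "valid"))
    expect_lte(v$max_row_deviation, 1e-12)
    expect_gte(v$min_entry, 0)
  }
})

test_that("validate_cube flags a corrupted row with its index", {
  arch <- homing_suppression_architecture()
  arch$cube$tau[2, 3, 1] <- arch$cube$tau[2, 3, 1] + 0.01
  v <- validate_cube(arch$cube)
  expect_false(v$ok)
  expect_identical(unname(v$bad_rows[1, ]), c(2L, 3L))
})

test_that("zero-activity drives collapse to the Mendelian cube exactly", {
  null_drive <- drive_params(cleavage = 0, hdr = 0, resistance = 0)
  no_cost <- fitness_params(0, 0, 0)
  men_map <- locus_map(locus("cas9", "Y", c("W", "C")),
                       locus("grna", "autosomal", c("W", "G", "R", "B")))
  men <- mendelian_architecture(men_map)
  drv <- split_drive_architecture("Y", null_drive, no_cost)
  expect_lt(max(abs(drv$cube$tau - men$cube$tau)), 1e-12)
  expect_equal(drv$traits$fecundity, men$traits$fecundity)
  expect_equal(drv$traits$mortality_mult, men$traits$mortality_mult)
  # null shredder: Mendelian tensor, scaling identically 1
  sh <- x_shredder_architecture("Y", shredder_params(0, 0), no_cost)
  men2 <- mendelian_architecture(sh$map)
  expect_lt(max(abs(sh$cube$tau - men2$cube$tau)), 1e-12)
  expect_true(all(abs(sh$cube$scaling - 1) < 1e-12))
})

test_that("split-drive cubes agree with the brute-force allele-fate oracle", {
  c <- 0.95; h <- 1; rho <- 0.02; inframe <- 1/3
  arch <- split_drive_architecture("Y", drive_params(c, h, rho, inframe))
  grna_pairs <- list(c("W", "W"), c("G", "W"), c("G", "G"), c("G", "R"),
                     c("G", "B"), c("R", "W"), c("B", "B"))
  for (mg in grna_pairs) for (fg in grna_pairs) for (fc in c(TRUE, FALSE)) {
    want <- oracle_split_Y_cross(mg, fg, fc, c, h, rho, inframe)
    mother <- paste0("F|grna:", paste(sort(factor(mg, c("W","G","R","B"))), collapse = "/"))
    father <- paste0("M|cas9:", if (fc) "C" else "W", ";grna:",
                     paste(sort(factor(fg, c("W","G","R","B"))), collapse = "/"))
    got <- cube_row(arch, mother, father)
    expect_dist_equal(got, want)
  }
})

test_that("drive-heterozygote germlines produce the expected gamete bias", {
  # c = 0.99, h = 1, rho = 0: W->G at 0.99 per copy => gametes {G: 0.995, W: 0.005}
  arch <- split_drive_architecture("Y", drive_params(0.99, 1, 0))
  row <- cube_row(arch, "F|grna:W/W", "M|cas9:C;grna:W/G")
  # offspring G-bearing fraction equals the paternal G gamete share
  g_off <- sum(row[has_allele(arch$gset, "grna", "G")])
  expect_equal(g_off, 0.995, tolerance = 1e-12)
  # homing suppression: same arithmetic at the single drive locus
  hs <- homing_suppression_architecture(drive_params(0.99, 1, 0))
  row2 <- cube_row(hs, "F|drive:W/W", "M|drive:W/H")
  expect_equal(sum(row2[has_allele(hs$gset, "drive", "H")]), 0.995,
               tolerance = 1e-12)
})

test_that("Y-linked Cas9 reaches all sons and no daughters", {
  arch <- split_drive_architecture("Y")
  row <- cube_row(arch, arch$wild_female, arch$release_label)
  male <- arch$gset$legend$sex == "M"
  carries <- has_allele(arch$gset, "cas9", "C")
  expect_equal(sum(row[male & carries]) / sum(row[male]), 1)
  expect_equal(sum(row[!male & carries]), 0)
})

test_that("X-shredding distorts the sex ratio and scales cross fecundity", {
  # e = 1, rho_x = 0: all offspring male, all carry the shredder, scaling 1/2
  a1 <- x_shredder_architecture("Y", shredder_params(1, 0))
  row <- cube_row(a1, a1$wild_female, a1$release_label)
  male <- a1$gset$legend$sex == "M"
  expect_equal(sum(row[male]), 1)
  expect_equal(sum(row[male & has_allele(a1$gset, "shredder", "S")]), 1)
  fi <- match(a1$wild_female, rownames(a1$cube$scaling))
  mj <- match(a1$release_label, colnames(a1$cube$scaling))
  expect_equal(a1$cube$scaling[fi, mj], 0.5)
  # e = 0.95: male fraction 0.5/0.525, scaling 0.525
  a2 <- x_shredder_architecture("Y", shredder_params(0.95, 0))
  row2 <- cube_row(a2, a2$wild_female, a2$release_label)
  expect_equal(sum(row2[a2$gset$legend$sex == "M"]), 0.5 / 0.525, tolerance = 1e-12)
  expect_equal(a2$cube$scaling[fi, mj], 0.525)
  # sperm-excess mode: same sex ratio, fecundity reduced only by the stated cost
  a3 <- x_shredder_architecture("Y", shredder_params(0.95, 0, fertility_cost = 0.1))
  expect_equal(a3$cube$tau, a2$cube$tau)
  expect_equal(a3$cube$scaling[fi, mj], 0.9)
  # wild-type fathers keep scaling 1 in both modes
  wj <- match(a3$wild_male, colnames(a3$cube$scaling))
  expect_equal(unname(a3$cube$scaling[fi, wj]), 1)
  # X-linked shredder is an unsupported architecture
  expect_error(x_shredder_architecture("X"), "unsupported")
})

test_that("female fertility flags follow the fertility-gene genotype", {
  arch <- homing_suppression_architecture()
  sterile <- arch$traits$label[!arch$traits$fertile]
  expect_setequal(sterile, c("F|drive:H/H", "F|drive:H/B", "F|drive:B/B"))
  # R restores function: H/R females fertile
  hr <- arch$traits[arch$traits$label == "F|drive:H/R", ]
  expect_true(hr$fertile)
})

test_that("maternal deposition converts zygotic wild-type targets", {
  arch <- split_drive_architecture("autosomal",
                                   drive_params(0.9, 1, 0, inframe = 1/3,
                                                deposition = 1))
  v <- validate_cube(arch$cube)
  expect_true(v$ok)
  # Cas9/gRNA mother: no W allele survives at the gRNA locus in her offspring
  row <- cube_row(arch, "F|cas9:W/C;grna:W/G", "M|cas9:W/W;grna:W/W")
  w_off <- has_allele(arch$gset, "grna", "W")
  expect_equal(sum(row[w_off]), 0)
  # wild-type mother rows untouched by deposition
  arch0 <- split_drive_architecture("autosomal", drive_params(0.9, 1, 0))
  expect_equal(cube_row(arch, arch$wild_female, "M|cas9:W/C;grna:W/G"),
               cube_row(arch0, arch0$wild_female, "M|cas9:W/C;grna:W/G"))
})
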