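hexagon <- function(center = c(0, 0, 0), radius = 1.4, tilt_deg = 0) {
  ang <- seq(0, 300, by = 60) * pi / 180
  P <- cbind(radius * cos(ang), radius * sin(ang), 0)
  if (tilt_deg != 0) {
    th <- tilt_deg * pi / 180
    R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
                3, 3, byrow = TRUE)
    P <- P %*% t(R)
  }
  sweep(P, 2, center, `+`)
}

one_residue_model <- function(extra = NULL) {
  at <- data.frame(residue_index = 1L, residue_name = "A",
                   atom_name = c("C2", "C4", "C6"), element = "C",
                   x = hexagon()[c(1, 3, 5), 1],
                   y = hexagon()[c(1, 3, 5), 2],
                   z = 0)
  if (!is.null(extra)) at <- rbind(at, extra)
  rna_model(at)
}

test_that("an amidinium-like group yields one charged-group cation center", {
  co <- rbind(c(0, 0, 0), c(1.3, 0, 0), c(-0.65, 1.1, 0))
  p <- make_simple_pose(co, elements = c("C", "N", "N"),
                        charges = c(0L, 1L, 0L),
                        bonds = rbind(c(1, 2, 1), c(1, 3, 2)),
                        scaffold = 1:3)
  cn <- assign_centers(p)
  expect_equal(nrow(cn$cations), 1)
  expect_equal(as.numeric(cn$cations[1, c("x", "y", "z")]),
               colMeans(co[1:2, ]))  # charged N plus its bonded C
})

test_that("RNA typing follows the per-nucleotide dictionary", {
  m <- make_idealized_helix(10)$models[[1]]
  cn <- assign_centers(m)
  g_res <- 5  # the G inserted mid-helix
  expect_equal(m$atoms$residue_name[m$atoms$residue_index == g_res][1], "G")
  g_d <- cn$donors[cn$donors$residue_index == g_res, ]
  expect_setequal(g_d$ref, c("N1", "N2", "O2'"))
  g_a <- cn$acceptors[cn$acceptors$residue_index == g_res, ]
  expect_setequal(g_a$ref, c("O6", "N7", "O2'", "O1P", "O2P"))
  g_an <- cn$anions[cn$anions$residue_index == g_res, ]
  expect_setequal(g_an$ref, c("O1P", "O2P"))
  expect_true(all(g_an$moiety == "phosphate"))
  expect_equal(sum(cn$rings$residue_index == g_res), 1)
})

test_that("a benzene fragment is one planar aromatic ring", {
  p <- make_simple_pose(hexagon(),
                        bonds = cbind(1:6, c(2:6, 1), 1))
  cn <- assign_centers(p)
  expect_equal(nrow(cn$rings), 1)
  expect_equal(as.numeric(cn$rings[1, c("x", "y", "z")]), c(0, 0, 0),
               tolerance = 1e-9)
  expect_equal(abs(as.numeric(cn$rings[1, c("nx", "ny", "nz")])[3]), 1,
               tolerance = 1e-9)
  expect_equal(sqrt(sum(as.numeric(
    cn$rings[1, c("nx", "ny", "nz")])^2)), 1, tolerance = 1e-9)
})

test_that("unknown elements are skipped with a warning", {
  p <- make_simple_pose(rbind(c(0, 0, 0), c(1.4, 0, 0)),
                        elements = c("C", "Xx"), scaffold = 1:2)
  expect_warning(assign_centers(p), "Xx")
})

test_that("a distant ligand produces no interactions", {
  p <- make_simple_pose(hexagon(center = c(30, 0, 0)),
                        bonds = cbind(1:6, c(2:6, 1), 1))
  inter <- detect_interactions(p, one_residue_model())
  expect_equal(nrow(inter), 0)
})

test_that("a charged nitrogen near a phosphate oxygen scores one hydrogen
           bond and one cation-anion at the constructed distances", {
  o1p <- data.frame(residue_index = 1L, residue_name = "A",
                    atom_name = "O1P", element = "O",
                    x = 10, y = 0, z = 0)
  m <- one_residue_model(extra = o1p)
  p <- make_simple_pose(matrix(c(12.9, 0, 0), 1, 3),
                        elements = "N", charges = 1L,
                        bonds = matrix(integer(0), 0, 3),
                        scaffold = 1L)
  inter <- detect_interactions(p, m)
  expect_equal(sum(inter$category == "hbond"), 1)
  expect_equal(inter$distance[inter$category == "hbond"], 2.9,
               tolerance = 1e-9)
  expect_equal(sum(inter$category == "cation_anion"), 1)
  expect_equal(inter$distance[inter$category == "cation_anion"], 2.9,
               tolerance = 1e-9)
  # a neutral donor at the same spot loses the cation-anion contact
  p0 <- make_simple_pose(matrix(c(12.9, 0, 0), 1, 3),
                         elements = "N", charges = 0L,
                         bonds = matrix(integer(0), 0, 3), scaffold = 1L)
  inter0 <- detect_interactions(p0, m)
  expect_equal(sum(inter0$category == "hbond"), 1)
  expect_equal(sum(inter0$category == "cation_anion"), 0)
})

test_that("parallel stacked rings at 3.5 A are one pi-stacking contact", {
  p <- make_simple_pose(hexagon(center = c(0, 0, 3.5), tilt_deg = 5),
                        bonds = cbind(1:6, c(2:6, 1), 1))
  inter <- detect_interactions(p, one_residue_model())
  expect_equal(sum(inter$category == "pi_stacking"), 1)
  expect_equal(inter$distance[inter$category == "pi_stacking"], 3.5,
               tolerance = 0.01)
  # far offset parallel rings fail the offset criterion
  p_off <- make_simple_pose(hexagon(center = c(4, 0, 3.5)),
                            bonds = cbind(1:6, c(2:6, 1), 1))
  inter_off <- detect_interactions(p_off, one_residue_model())
  expect_equal(sum(inter_off$category == "pi_stacking"), 0)
})

test_that("histograms bin by distance with exact conservation", {
  cfg <- fingerprint_config()
  empty <- fingerprint_histogram(
    data.frame(category = character(0), distance = numeric(0),
               rna_residue = integer(0), rna_moiety = character(0)), cfg)
  expect_true(all(empty == 0))

  one <- fingerprint_histogram(
    data.frame(category = "hbond", distance = 3.0,
               rna_residue = 1L, rna_moiety = "base"), cfg)
  expect_equal(unname(one["hbond", 14]), 1)  # bin 13, zero-based
  expect_equal(sum(one), 1)

  set.seed(8)
  rand <- data.frame(
    category = sample(FP_CATEGORIES, 200, replace = TRUE),
    distance = runif(200, 0, 10), rna_residue = 1L, rna_moiety = "base")
  H <- fingerprint_histogram(rand, cfg)
  in_range <- rand$distance >= 2 & rand$distance < 8
  for (cat in FP_CATEGORIES) {
    expect_equal(unname(sum(H[cat, ])),
                 sum(in_range & rand$category == cat))
  }
  expect_equal(attr(H, "dropped"), sum(!in_range))

  # adding one in-range interaction changes exactly one bin by +1
  H2 <- fingerprint_histogram(
    rbind(rand, data.frame(category = "lipophilic", distance = 5.03,
                           rna_residue = 2L, rna_moiety = "base")), cfg)
  dd <- H2 - H
  expect_equal(sum(dd), 1)
  expect_equal(sum(dd != 0), 1)
  expect_equal(unname(dd["lipophilic", floor((5.03 - 2) / 0.075) + 1]), 1)
})

test_that("typing and detection are invariant to atom input order", {
  p <- fx_planted$poses[[3]]
  set.seed(9)
  perm <- sample(nrow(p$atoms))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  p2 <- ligand_pose(p$ligand_id, p$site_tag, p$conformation_tag,
                    p$program_tag,
                    atoms = p$atoms[perm, ],
                    bonds = cbind(inv[p$bonds[, 1]], inv[p$bonds[, 2]],
                                  p$bonds[, 3]),
                    scaffold_atoms = inv[p$scaffold_atoms])
  i1 <- detect_interactions(p, fx_model)
  i2 <- detect_interactions(p2, fx_model)
  key <- function(x) {
    with(x, sort(paste(category, round(distance, 9), rna_residue,
                       rna_moiety)))
  }
  expect_equal(key(i2), key(i1))
})

test_that("fingerprint matrix rows equal per-pose histograms", {
  poses <- fx_planted$poses[1:6]
  M <- fingerprint_matrix(poses, fx_model)
  expect_equal(dim(M), c(6, 7 * 80))
  for (i in c(1, 4)) {
    H <- fingerprint_histogram(detect_interactions(poses[[i]], fx_model))
    expect_equal(unname(M[i, ]), as.vector(t(H)))
  }
  expect_equal(attr(M, "tags")$ligand_id,
               vapply(poses, `[[`, character(1), "ligand_id"))
})

test_that("conformation tags must resolve against the model set", {
  p <- fx_planted$poses[[1]]
  p$conformation_tag <- "m99"
  expect_error(fingerprint_matrix(list(p), fx_ensemble), "m99")
})

test_that("average profiles are per-group arithmetic means", {
  r0 <- rep(0, 10); r2 <- rep(2, 10)
  M <- rbind(a = r0, b = r2)
  prof <- average_profile(M, c("g", "g"))
  expect_true(all(prof == 1))
  single <- average_profile(matrix(r2, 1), "x")
  expect_equal(unname(single[1, ]), r2)
  expect_error(average_profile(M[0, , drop = FALSE], character(0)),
               "empty")

  # planted lipophilic peaks: bimodal 4.5/5.5 vs sharp 5.0
  mk_rows <- function(dists, n) {
    t(vapply(seq_len(n), function(i) {
      d <- dists[sample.int(length(dists), 30, replace = TRUE)] +
        rnorm(30, 0, 0.02)
      as.vector(t(fingerprint_histogram(
        data.frame(category = "lipophilic", distance = d,
                   rna_residue = 1L, rna_moiety = "base"))))
    }, numeric(560)))
  }
  set.seed(10)
  rows <- rbind(mk_rows(c(4.5, 5.5), 20), mk_rows(5.0, 20))
  grp <- rep(c("siteA", "siteB"), each = 20)
  prof2 <- average_profile(rows, grp)
  lip <- (which(FP_CATEGORIES == "lipophilic") - 1) * 80 + 1:80
  edges <- 2 + 0.075 * (0:79)
  peakA <- edges[which.max(prof2["siteA", lip])]
  peakB <- edges[which.max(prof2["siteB", lip])]
  expect_lt(abs(peakB - 5.0), 0.1)
  expect_true(min(abs(peakA - c(4.5, 5.5))) < 0.1)
})
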