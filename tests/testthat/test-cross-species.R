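toy_connectome <- function(labels, seed = 1) {
  set.seed(seed)
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  m[upper.tri(m)] <- runif(sum(upper.tri(m)), 0, 10)
  m + t(m)
}

test_that("packaged homology table has 27 homologs in both species", {
  tab <- homology_table()
  for (sp in c("human", "macaque")) {
    expect_length(unique(tab$homolog[tab$species == sp]), 27)
  }
  expect_setequal(unique(tab$lobe),
                  c("frontal", "parietal", "temporal", "occipital"))
  # every homolog present for both species
  by_hom <- table(unique(tab[, c("homolog", "species")])$homolog)
  expect_true(all(by_hom == 2))
  # tool-use nodes are covered (seeds live outside the homolog list)
  expect_true(all(setdiff(tool_use_nodes(), mt_seeds()) %in% tab$homolog))
})

test_that("common-space projection aggregates many-to-one labels by summation", {
  labels <- c(mt_seeds(), "x1", "x2", "y1")
  m <- matrix(0, 6, 6, dimnames = list(labels, labels))
  m["MST", c("x1", "x2", "y1")] <- c(1, 2, 5)
  m["MT", c("x1", "x2", "y1")] <- c(3, 1, 2)
  m["FST", c("x1", "x2", "y1")] <- c(0, 0, 7)
  m <- pmax(m, t(m))
  hom <- data.frame(
    species = "human",
    atlas_label = c("x1", "x2", "y1"),
    homolog = c("H1", "H1", "H2"),
    lobe = c("parietal", "parietal", "temporal")
  )
  prof <- project_to_common_space(m, hom, "human")
  expect_equal(prof$strengths["MST", "H1"], 3)  # 1 + 2
  expect_equal(prof$strengths["MT", "H1"], 4)
  expect_equal(prof$strengths["FST", "H2"], 7)
  expect_equal(dim(prof$strengths), c(3, 2))
  expect_error(project_to_common_space(m[1:4, 1:4], hom, "human"), "missing")
})

test_that("joint ranks cover the full seed-by-homolog table with average ties", {
  labels <- c(mt_seeds(), sprintf("t%02d", 1:27))
  m <- toy_connectome(labels, seed = 3)
  hom <- synthetic_homology_table(labels)
  prof <- project_to_common_space(m, hom, "human")
  expect_equal(sort(as.vector(prof$joint_ranks)), as.numeric(1:81))
  # invariance of ranks under a strictly increasing transform of strengths
  m2 <- m^2  # strengths nonnegative, so x^2 is strictly increasing
  prof2 <- project_to_common_space(m2, hom, "human")
  r1 <- rank(prof$strengths)
  r2 <- rank(vapply(as.vector(prof$strengths), function(x) x, numeric(1))^2)
  expect_equal(as.vector(prof2$joint_ranks)[order(r1)], sort(r2))
  # all-equal strengths -> all average ranks equal
  meq <- matrix(1, 30, 30, dimnames = list(labels, labels))
  diag(meq) <- 0
  peq <- project_to_common_space(meq, hom, "human")
  expect_true(all(peq$joint_ranks == peq$joint_ranks[1, 1]))
})

test_that("cross-species seed correlation is symmetric and Bonferroni n = 3", {
  labels <- c(mt_seeds(), sprintf("t%02d", 1:27))
  hom <- synthetic_homology_table(labels)
  pa <- project_to_common_space(toy_connectome(labels, 5), hom, "human")
  pb <- project_to_common_space(toy_connectome(labels, 6),
                                hom[hom$species == "macaque", ], "macaque")
  r_ab <- cross_species_seed_correlation(pa, pb, "MT")
  r_ba <- cross_species_seed_correlation(pb, pa, "MT")
  expect_equal(r_ab$rho, r_ba$rho)
  expect_equal(r_ab$p_adjusted, min(1, r_ab$p_value * 3))
  expect_equal(r_ab$n_homologs, 27)
  r_self <- cross_species_seed_correlation(pa, pa, "MST")
  expect_equal(r_self$rho, 1)
})

test_that("identical and reversed fingerprints give rho 1 and -1", {
  mk_prof <- function(v) {
    s <- matrix(rep(v, each = 3), 3, length(v),
                dimnames = list(mt_seeds(), sprintf("H%d", seq_along(v))))
    structure(list(strengths = s, joint_ranks = s, species = "x",
                   lobes = setNames(rep("frontal", length(v)),
                                    colnames(s))),
              class = "common_space_profile")
  }
  v <- c(4, 1, 9, 2, 7)
  expect_equal(cross_species_seed_correlation(mk_prof(v), mk_prof(v),
                                              "MT")$rho, 1)
  expect_equal(cross_species_seed_correlation(mk_prof(v), mk_prof(-v),
                                              "MT")$rho, -1)
})

test_that("tracer symmetrization averages bidirectional entries", {
  tr <- data.frame(
    source = c("A", "B", "A"),
    target = c("B", "A", "C"),
    strength = c(2, 4, 5)
  )
  s <- symmetrize_tracer(tr)
  expect_equal(s$strength[s$region_a == "A" & s$region_b == "B"], 3)
  expect_equal(s$strength[s$region_a == "A" & s$region_b == "C"], 5)
  # idempotent on an already-symmetric table
  sym <- data.frame(source = c("A", "B"), target = c("B", "A"),
                    strength = c(3, 3))
  expect_equal(symmetrize_tracer(sym)$strength, 3)
  dup <- data.frame(source = c("A", "A"), target = c("B", "B"),
                    strength = c(1, 2))
  expect_error(symmetrize_tracer(dup), "duplicate")
})

test_that("tracer concordance is rank-invariant and respects the mapping rules", {
  dti <- setNames(c(5, 2, 9, 1, 7, 3), sprintf("r%d", 1:6))
  # noise-free monotone transform of the DTI vector -> rho = 1
  tr <- data.frame(
    source = names(dti), target = "MT", strength = exp(dti)
  )
  expect_equal(tracer_concordance(dti, tr, seed = "MT")$rho, 1)
  # reversed ranking -> rho = -1
  tr_rev <- data.frame(source = names(dti), target = "MT",
                       strength = -dti)
  expect_equal(tracer_concordance(dti, tr_rev, seed = "MT")$rho, -1)
  # unmappable tracer regions are dropped; mapped ones aggregate by sum
  tr_map <- data.frame(
    source = c("u1", "u2", "u3", "u4", "junk"),
    target = "MT",
    strength = c(1, 2, 10, 4, 99)
  )
  mapping <- c(u1 = "r1", u2 = "r1", u3 = "r2", u4 = "r3")
  dti2 <- setNames(c(3, 30, 4, 5), c("r1", "r2", "r3", "r4"))
  conc <- tracer_concordance(dti2, tr_map, seed = "MT",
                             region_mapping = mapping)
  expect_equal(conc$n_regions, 3)
  # aggregated tracer strengths (r1 = 1 + 2, r2 = 10, r3 = 4) share the
  # DTI ranking of (3, 30, 4) -> perfect concordance
  expect_equal(conc$rho, 1)
  expect_error(
    tracer_concordance(dti2[1:2], tr_map, seed = "MT",
                       region_mapping = mapping[1:3]),
    "3 shared"
  )
  # one-directional mode skips averaging
  tr_dir <- data.frame(source = names(dti), target = "MT", strength = dti)
  expect_equal(tracer_concordance(dti, tr_dir, seed = "MT",
                                  symmetrize = FALSE)$rho, 1)
})
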