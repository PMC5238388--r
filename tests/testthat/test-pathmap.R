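# map-building test systems: short relaxation times keep the effective sample
# count high at modest series length (power for the shuffle-null threshold)
map_chain_data <- function(seed, n_res = 5, length_ns = 1500) {
  sys <- make_system(n_res, edges = chain_edges(seq_len(n_res)),
                     tau_ns = 2:6, seed = seed)
  generate_synthetic(sys, length_ns, 0.1, seed = 1000 + seed)
}

test_that("the planted dof pair and direction win the per-pair selection", {
  sys <- make_system(2, dofs = c("phi", "psi"),
                     edges = data.frame(from_res = 1, from_dof = "phi",
                                        to_res = 2, to_dof = "phi",
                                        strength = 0.6),
                     tau_ns = c(2, 3, 2.5, 3.5), seed = 21)
  d <- generate_synthetic(sys, 1200, 0.1, seed = 22, positions = FALSE)
  by_res <- split(d$series, vapply(d$series, function(s) s$res_index, 1L))
  fl <- lapply(by_res, function(g) {
    names(g) <- vapply(g, function(s) s$dof, ""); lapply(g, fluctuations)
  })
  dc <- best_dof_pair(fl[["1"]], fl[["2"]], max_lag_ns = 25, n_null = 60,
                      seed = 23)
  expect_equal(c(dc$dof_i, dc$dof_j), c("phi", "phi"))
  expect_equal(dc$direction, "i->j")
  expect_true(dc$significant)
  expect_equal(nrow(dc$table), 4L)        # 2 x 2 dof pairs, both directions each
  # winner magnitude bound: best |F| is the table maximum
  expect_equal(dc$F_best, max(abs(c(dc$table$F_fwd, dc$table$F_rev))))
})

test_that("maps have the right combinatorics and mark missing residues", {
  d <- map_chain_data(31, n_res = 5, length_ns = 400)
  map <- build_map(d$series, max_lag_ns = 20, n_null = 0, seed = 1)
  expect_equal(nrow(map$cells), 10L)      # 5 choose 2
  expect_equal(sum(map$cells$status == "ok"), 10L)

  # drop residue 3: its cells are marked, not silently zeroed
  drop3 <- d$series[vapply(d$series, function(s) s$res_index != 3L, TRUE)]
  map3 <- build_map(drop3, n_res = 5, max_lag_ns = 20, n_null = 0, seed = 1)
  expect_equal(sum(map3$cells$status == "missing"), 4L)
  expect_true(all(is.na(map3$cells$F_best[map3$cells$status == "missing"])))

  # every populated cell keeps both directions with the winner at least as big
  ok <- map$cells[map$cells$status == "ok", ]
  expect_true(all(pmax(abs(ok$F_fwd), abs(ok$F_rev)) == abs(ok$F_best)))
})

test_that("downstream sets follow the planted drive and empty out when reversed", {
  sys <- make_system(4, edges = star_edges(1, 2:4), tau_ns = c(2, 3, 4, 5),
                     seed = 41)
  d <- generate_synthetic(sys, 1500, 0.1, seed = 42, positions = FALSE)
  map <- build_map(d$series, max_lag_ns = 25, n_null = 80, seed = 43)
  expect_setequal(downstream_set(map, 1), 2:4)

  rev_edges <- data.frame(from_res = 2:4, from_dof = "phi", to_res = 1,
                          to_dof = "phi", strength = 0.6)
  sysr <- make_system(4, edges = rev_edges, tau_ns = c(2, 3, 4, 5), seed = 41)
  dr <- generate_synthetic(sysr, 1500, 0.1, seed = 42, positions = FALSE)
  mapr <- build_map(dr$series, max_lag_ns = 25, n_null = 80, seed = 43)
  expect_length(downstream_set(mapr, 1), 0L)

  # uncorrelated map: empty downstream set everywhere
  sys0 <- make_system(4, tau_ns = c(2, 3, 4, 5), seed = 44)
  d0 <- generate_synthetic(sys0, 800, 0.1, seed = 45, positions = FALSE)
  map0 <- build_map(d0$series, max_lag_ns = 25, n_null = 80, seed = 46)
  expect_lte(length(unlist(lapply(1:4, downstream_set, map = map0))), 1L)
})

test_that("path construction steps to the closest downstream residue with deterministic ties", {
  # hand-built map: 1 drives 2 and 3; 2 drives nothing; tie in distance
  cells <- data.frame(
    i = c(1, 1, 2), j = c(2, 3, 3), status = "ok",
    dof_i = "phi", dof_j = "phi", direction = c("i->j", "i->j", "j->i"),
    F_fwd = c(4, 3, 1), F_rev = c(1, 1, 2), tau_fwd = 10, tau_rev = 8,
    F_best = c(4, 3, 2), pearson = 0.5, threshold = 1.5,
    significant = c(TRUE, TRUE, FALSE), tie = FALSE)
  map <- structure(list(cells = cells, n_res = 3, q = 0.95, n_null = 0,
                        seed = 1), class = "correlation_map")
  dtable <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), kind = "alpha-alpha",
                       mean_nm = c(0.5, 0.5, 0.4), var_nm2 = 0)
  p <- build_path(map, dtable, 1)
  expect_equal(p$res, c(1, 2))            # tie 2 vs 3 resolves to lower index
  expect_true(p$tie[2])
  expect_equal(p$F_max[2], 4)

  expect_error(build_path(map, dtable, 9), "absent")

  # start residue with empty downstream set: single-residue path
  p3 <- build_path(map, dtable, 3)
  expect_equal(p3$res, 3)
})

test_that("a planted chain is recovered end to end through map + distances + path", {
  d <- map_chain_data(51)
  map <- build_map(d$series, max_lag_ns = 30, n_s = 80, n_null = 100, seed = 52)
  dtab <- distance_table(d, t(combn(5, 2)), "alpha-alpha")
  p <- build_path(map, dtab, 1)
  expect_equal(as.integer(p$res), 1:5)
  # determinism: identical inputs and seeds give identical maps and paths
  map2 <- build_map(d$series, max_lag_ns = 30, n_s = 80, n_null = 100, seed = 52)
  expect_identical(map$cells, map2$cells)
  expect_identical(as.data.frame(build_path(map2, dtab, 1)), as.data.frame(p))
})

test_that("amplitude-versus-variance pairs each cell with the right distance kind", {
  # rigid geometry: all variances zero
  sys <- make_system(3, edges = chain_edges(1:3), tau_ns = c(2, 3, 4),
                     jitter_nm = 0, seed = 61)
  d <- generate_synthetic(sys, 1200, 0.1, seed = 62)
  map <- build_map(d$series, max_lag_ns = 25, n_null = 60, seed = 63)
  dtab <- distance_table(d, t(combn(3, 2)), "alpha-alpha")
  av <- amplitude_vs_variance(map, dtab)
  expect_true(all(av$var_nm2 == 0))
  expect_true(all(av$kind == "alpha-alpha"))   # phi-phi pairs are backbone-backbone

  # empty map (nothing significant): empty table
  empty <- map
  empty$cells$significant <- FALSE
  expect_equal(nrow(amplitude_vs_variance(empty, dtab)), 0L)

  # by-coupling jitter: coupled pairs sit at lower variance than uncoupled
  sysj <- make_system(4, edges = chain_edges(1:2), tau_ns = c(2, 3, 4, 5),
                      jitter_mode = "by-coupling", seed = 64)
  dj <- generate_synthetic(sysj, 300, 0.1, seed = 65)
  dtj <- distance_table(dj, t(combn(4, 2)), "alpha-alpha")
  v12 <- dtj$var_nm2[dtj$i == 1 & dtj$j == 2]
  v34 <- dtj$var_nm2[dtj$i == 3 & dtj$j == 4]
  expect_lt(v12, v34 / 5)
})

test_that("peak strength tracks the Pearson coefficient across coupling strengths", {
  # disjoint pairs with increasing planted strength inside one system
  edges <- data.frame(from_res = c(1, 3, 5, 7), from_dof = "phi",
                      to_res = c(2, 4, 6, 8), to_dof = "phi",
                      strength = c(0.1, 0.25, 0.45, 0.7))
  sys <- make_system(8, edges = edges, tau_ns = 2.5, seed = 71)
  d <- generate_synthetic(sys, 1200, 0.1, seed = 72, positions = FALSE)
  map <- build_map(d$series, max_lag_ns = 25, n_null = 0, seed = 73)
  pv <- peak_vs_pearson(map)
  expect_equal(nrow(pv$table), 28L)
  expect_gt(pv$cor_strength, 0)
  # among the genuinely coupled (functional) pairs the relation is monotone
  planted <- merge(pv$table, data.frame(i = edges$from_res, j = edges$to_res))
  expect_equal(order(planted$F_max), order(edges$strength))
  expect_equal(cor(planted$F_max, planted$abs_pearson, method = "spearman"), 1)
})

test_that("map and path exports are tidy TSV files", {
  dir <- withr::local_tempdir()
  d <- map_chain_data(81, n_res = 3, length_ns = 300)
  map <- build_map(d$series, max_lag_ns = 15, n_null = 20, seed = 82)
  write_map_tsv(map, file.path(dir, "map.tsv"))
  write_map_matrix(map, file.path(dir, "mat.tsv"))
  mt <- utils::read.table(file.path(dir, "map.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(mt), 3L)
  mm <- as.matrix(utils::read.table(file.path(dir, "mat.tsv"), sep = "\t"))
  expect_equal(dim(mm), c(3L, 3L))
  dtab <- distance_table(d, t(combn(3, 2)), "alpha-alpha")
  p <- build_path(map, dtab, 1)
  write_path_tsv(p, file.path(dir, "path.tsv"))
  pt <- utils::read.table(file.path(dir, "path.tsv"), header = TRUE, sep = "\t")
  expect_equal(pt$res[1], 1)
})
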