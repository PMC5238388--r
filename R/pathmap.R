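# group a flat res<idx>_<dof> series list by residue
split_by_residue <- function(series_set) {
  res <- vapply(series_set, function(s) s$res_index, 1L)
  lapply(split(series_set, res), function(g) {
    names(g) <- vapply(g, function(s) s$dof, "")
    g
  })
}

# e-folding correlation time of a fluctuation series, in frames
corr_time_frames <- function(f, max_frac = 0.25) {
  n <- length(f$dev_deg)
  L <- max(2L, floor(max_frac * n))
  ac <- cross_sums(f$dev_deg, f$dev_deg, L) / ((n - 0:L) * f$var_deg2)
  below <- which(ac < exp(-1))
  if (length(below)) below[1] - 1L else L
}

# all dof-pair x direction Laplace summaries for one residue pair.
# fl_i / fl_j: named lists of fluct_series keyed by dof.
pair_table <- function(fl_i, fl_j, max_lag_ns, n_s, min_count) {
  rows <- list()
  for (a in names(fl_i)) for (b in names(fl_j)) {
    fwd <- laplace_extremum(laplace_transform(
      tdcf_estimate(fl_i[[a]], fl_j[[b]], max_lag_ns, min_count), n_s = n_s))
    rev <- laplace_extremum(laplace_transform(
      tdcf_estimate(fl_j[[b]], fl_i[[a]], max_lag_ns, min_count), n_s = n_s))
    rows[[paste(a, b)]] <- data.frame(
      dof_i = a, dof_j = b,
      F_fwd = fwd$F_ext, tau_fwd = fwd$tau_ns, bnd_fwd = fwd$boundary,
      F_rev = rev$F_ext, tau_rev = rev$tau_ns, bnd_rev = rev$boundary)
  }
  do.call(rbind, rows)
}

shift_fluct <- function(f, offset) {
  n <- length(f$dev_deg)
  offset <- ((offset - 1L) %% n) + 1L
  f$dev_deg <- f$dev_deg[c(offset:n, seq_len(offset - 1L))]
  f
}

#' Best dof pair and direction for one residue pair
#'
#' Computes Laplace-domain peak strengths for every defined dof pair of
#' residues i and j in both directions, selects the dof pair and direction
#' with the largest |F_ext| (the winner determines the direction of
#' correlation in the time domain: the forward curve having i at the earlier
#' time winning means j is downstream of i), and tests the winning strength
#' against a block-shuffle null: the 95th percentile of the same statistic
#' recomputed with residue j's series circularly shifted by random offsets of
#' at least one correlation time (`n_null` shuffles, seeded). Falling below
#' the threshold marks the pair uncorrelated.
#'
#' @param fl_i,fl_j Named (by dof) lists of [fluctuations()] series for the
#'   two residues.
#' @param i,j Residue indices (for bookkeeping; defaults taken from the series).
#' @param max_lag_ns Lag-grid extent passed to [tdcf_estimate()].
#' @param n_s Laplace grid size.
#' @param n_null Number of circular-shift shuffles for the null.
#' @param q Null quantile defining significance.
#' @param min_count Minimum per-lag observation count.
#' @param seed Seed for the shuffle offsets.
#' @return Object of class `directed_correlation`: winning dof pair,
#'   direction (`"i->j"` = j downstream of i), forward/reverse strengths and
#'   timescales, Pearson coefficient of the winning pair, the full table, the
#'   null threshold and the significance flag.
#' @export
best_dof_pair <- function(fl_i, fl_j, i = NULL, j = NULL,
                          max_lag_ns = NULL, n_s = 120L, n_null = 200L,
                          q = 0.95, min_count = 10L, seed = 1L) {
  fl_i <- lapply(fl_i, as_fluct); fl_j <- lapply(fl_j, as_fluct)
  i <- i %||% fl_i[[1]]$res_index; j <- j %||% fl_j[[1]]$res_index
  tab <- pair_table(fl_i, fl_j, max_lag_ns, n_s, min_count)
  stat_of <- function(tb) max(abs(c(tb$F_fwd, tb$F_rev)))
  stat <- stat_of(tab)
  # winner: joint argmax over dof pairs and directions; ties resolve to the
  # first row (dof order as supplied) and the forward direction, flagged
  mags <- cbind(abs(tab$F_fwd), abs(tab$F_rev))
  best_row <- which(apply(mags, 1, max) == stat)[1]
  tie <- sum(mags == stat) > 1L
  forward_wins <- mags[best_row, 1] >= mags[best_row, 2]
  null_stat <- rep(NA_real_, n_null)
  threshold <- NA_real_
  if (n_null > 0L) {
    n <- length(fl_i[[1]]$dev_deg)
    tmin <- max(vapply(c(fl_i, fl_j), corr_time_frames, 1L))
    set.seed(seed)
    offs <- sample(seq(tmin + 1L, n - tmin), n_null, replace = TRUE)
    for (k in seq_len(n_null)) {
      fj_s <- lapply(fl_j, shift_fluct, offset = offs[k])
      null_stat[k] <- stat_of(pair_table(fl_i, fj_s, max_lag_ns, n_s, min_count))
    }
    threshold <- unname(stats::quantile(null_stat, q, type = 6))
  }
  structure(
    list(i = i, j = j,
         dof_i = tab$dof_i[best_row], dof_j = tab$dof_j[best_row],
         direction = if (forward_wins) "i->j" else "j->i",
         F_fwd = tab$F_fwd[best_row], F_rev = tab$F_rev[best_row],
         tau_fwd = tab$tau_fwd[best_row], tau_rev = tab$tau_rev[best_row],
         F_best = stat, tie = tie,
         pearson = tdcf_pearson(fl_i[[tab$dof_i[best_row]]],
                                fl_j[[tab$dof_j[best_row]]]),
         table = tab, threshold = threshold,
         significant = if (n_null > 0L) stat > threshold else NA),
    class = "directed_correlation")
}

#' @export
print.directed_correlation <- function(x, ...) {
  cat(sprintf("directed_correlation %d-%d: best %s-%s %s, |F| = %.4g (thr %.4g, %s)\n",
              x$i, x$j, x$dof_i, x$dof_j, x$direction, x$F_best,
              x$threshold %||% NA,
              if (isTRUE(x$significant)) "significant" else "not significant"))
  invisible(x)
}

#' Directional residue-residue correlation map
#'
#' Applies [best_dof_pair()] to every residue pair i < j of a series set,
#' producing the upper-triangular map of winning dof pairs, directions,
#' strengths and timescales (N_res(N_res-1)/2 cells). Residues without series
#' yield cells marked `missing`, never silent zeros.
#'
#' @param series_set Flat named list of [angle_series] (names
#'   `res<idx>_<dof>`, as produced by [extract_all_series()] or
#'   [generate_synthetic()]).
#' @param n_res Map side; default the largest residue index present.
#' @inheritParams best_dof_pair
#' @param seed Base seed; each pair's shuffle offsets derive from it
#'   deterministically, so identical inputs give identical maps.
#' @return Object of class `correlation_map`: `cells` data frame, `n_res`,
#'   and the significance metadata (`q`, `n_null`, `seed`).
#' @export
build_map <- function(series_set, n_res = NULL, max_lag_ns = NULL,
                      n_s = 120L, n_null = 200L, q = 0.95,
                      min_count = 10L, seed = 1L) {
  by_res <- split_by_residue(series_set)
  by_res <- lapply(by_res, function(g) lapply(g, as_fluct))
  have <- as.integer(names(by_res))
  n_res <- n_res %||% max(have)
  cells <- list()
  for (i in seq_len(n_res - 1L)) for (j in (i + 1L):n_res) {
    if (!(i %in% have) || !(j %in% have)) {
      cells[[length(cells) + 1L]] <- data.frame(
        i = i, j = j, status = "missing", dof_i = NA, dof_j = NA,
        direction = NA, F_fwd = NA_real_, F_rev = NA_real_,
        tau_fwd = NA_real_, tau_rev = NA_real_, F_best = NA_real_,
        pearson = NA_real_, threshold = NA_real_, significant = NA, tie = NA)
      next
    }
    dc <- best_dof_pair(by_res[[as.character(i)]], by_res[[as.character(j)]],
                        i = i, j = j, max_lag_ns = max_lag_ns, n_s = n_s,
                        n_null = n_null, q = q, min_count = min_count,
                        seed = seed + 1009L * i + 9973L * j)
    cells[[length(cells) + 1L]] <- data.frame(
      i = i, j = j, status = "ok", dof_i = dc$dof_i, dof_j = dc$dof_j,
      direction = dc$direction, F_fwd = dc$F_fwd, F_rev = dc$F_rev,
      tau_fwd = dc$tau_fwd, tau_rev = dc$tau_rev, F_best = dc$F_best,
      pearson = dc$pearson, threshold = dc$threshold,
      significant = dc$significant, tie = dc$tie)
  }
  structure(list(cells = do.call(rbind, cells), n_res = n_res,
                 q = q, n_null = n_null, seed = seed),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("correlation_map: %d residues, %d cells, %d significant (q = %g, %d shuffles)\n",
              x$n_res, nrow(x$cells), sum(x$cells$significant %in% TRUE),
              x$q, x$n_null))
  invisible(x)
}

#' @export
#' @rdname build_map
#' @param x A `correlation_map`.
#' @param ... Unused.
as.matrix.correlation_map <- function(x, ...) {
  m <- matrix(0, x$n_res, x$n_res)
  cl <- x$cells[x$cells$significant %in% TRUE, ]
  for (k in seq_len(nrow(cl)))
    m[cl$i[k], cl$j[k]] <- if (cl$direction[k] == "i->j") abs(cl$F_best[k]) else -abs(cl$F_best[k])
  m
}

#' Downstream-correlated residues of a residue
#'
#' All partners whose winning direction makes them downstream of `r`
#' (perturbations at `r` precede responses at the partner), among the
#' significant cells of the map.
#'
#' @param map A `correlation_map`.
#' @param r Residue index.
#' @return Integer vector of residue indices (possibly empty).
#' @export
downstream_set <- function(map, r) {
  cl <- map$cells[map$cells$significant %in% TRUE, ]
  sort(c(cl$j[cl$i == r & cl$direction == "i->j"],
         cl$i[cl$j == r & cl$direction == "j->i"]))
}

#' Downstream-correlated residue path
#'
#' Starting from `start`, repeatedly steps to the spatially closest (smallest
#' mean Ca-Ca distance) downstream-correlated residue of the current residue,
#' skipping already-visited residues, until the downstream set is exhausted
#' (or a cycle guard of `n_res` steps trips). Equal distances resolve to the
#' lower residue index and are flagged.
#'
#' @param map A `correlation_map`.
#' @param dtable Distance table (see [distance_table()]) with `kind ==
#'   "alpha-alpha"` rows covering the significant pairs.
#' @param start Starting residue.
#' @return Object of class `tdcf_path`: data frame with one row per residue in
#'   path order and the step's dof pair, strength, timescale and mean Ca-Ca
#'   distance.
#' @export
build_path <- function(map, dtable, start) {
  have <- unique(c(map$cells$i, map$cells$j))
  if (!(start %in% have)) stop("start residue ", start, " absent from the map")
  dt_aa <- dtable[dtable$kind == "alpha-alpha", ]
  dist_of <- function(a, b) {
    r <- dt_aa[(dt_aa$i == a & dt_aa$j == b) | (dt_aa$i == b & dt_aa$j == a), ]
    if (nrow(r) == 0L) stop("no alpha-alpha distance for pair ", a, "-", b)
    r$mean_nm[1]
  }
  cell_of <- function(a, b) {
    map$cells[(map$cells$i == pmin(a, b)) & (map$cells$j == pmax(a, b)), ]
  }
  visited <- start
  rows <- data.frame(step = 0L, res = start, dof_i = NA, dof_j = NA,
                     F_max = NA_real_, tau_ns = NA_real_,
                     d_mean_nm = NA_real_, tie = FALSE)
  cur <- start
  for (step in seq_len(map$n_res)) {
    ds <- setdiff(downstream_set(map, cur), visited)
    if (length(ds) == 0L) break
    dd <- vapply(ds, dist_of, numeric(1), a = cur)
    nxt <- ds[dd == min(dd)]
    tie <- length(nxt) > 1L
    nxt <- min(nxt)
    cl <- cell_of(cur, nxt)
    rows <- rbind(rows, data.frame(
      step = step, res = nxt, dof_i = cl$dof_i, dof_j = cl$dof_j,
      F_max = abs(cl$F_best), tau_ns = if (cl$direction == "i->j") cl$tau_fwd else cl$tau_rev,
      d_mean_nm = min(dd), tie = tie))
    visited <- c(visited, nxt)
    cur <- nxt
  }
  structure(rows, class = c("tdcf_path", "data.frame"))
}

dofpair_kind <- function(dof_i, dof_j) {
  side_i <- dof_i == "chi1"; side_j <- dof_j == "chi1"
  ifelse(side_i & side_j, "beta-beta",
         ifelse(side_i | side_j, "alpha-beta", "alpha-alpha"))
}

#' Correlation amplitude versus distance variance
#'
#' For every significant cell, pairs the winning |F_ext| with the variance of
#' the matching inter-residue distance: backbone-backbone dof pairs use
#' var(d_alpha-alpha), backbone-sidechain use var(d_alpha-beta), and
#' sidechain-sidechain use var(d_beta-beta). Large correlation amplitudes
#' clustering at small distance variance indicates that large positional
#' fluctuations destroy dihedral dynamical correlations.
#'
#' @param map A `correlation_map`.
#' @param dtable Distance table covering the needed kinds (see
#'   [distance_table()]).
#' @return Tidy data frame (i, j, dof_i, dof_j, kind, F_max, var_nm2).
#' @export
amplitude_vs_variance <- function(map, dtable) {
  cl <- map$cells[map$cells$significant %in% TRUE, ]
  if (nrow(cl) == 0L)
    return(data.frame(i = integer(0), j = integer(0), dof_i = character(0),
                      dof_j = character(0), kind = character(0),
                      F_max = numeric(0), var_nm2 = numeric(0)))
  kind <- dofpair_kind(cl$dof_i, cl$dof_j)
  var_of <- function(a, b, k) {
    r <- dtable[dtable$kind == k &
                ((dtable$i == a & dtable$j == b) | (dtable$i == b & dtable$j == a)), ]
    if (nrow(r) == 0L) NA_real_ else r$var_nm2[1]
  }
  data.frame(i = cl$i, j = cl$j, dof_i = cl$dof_i, dof_j = cl$dof_j,
             kind = kind, F_max = abs(cl$F_best),
             var_nm2 = mapply(var_of, cl$i, cl$j, kind))
}

#' Peak strength and timescale versus Pearson coefficient
#'
#' Table of (|F_ext|, tau, |C(0)|) per populated cell, with Spearman rank
#' correlations: peak strengths track the equal-time Pearson coefficient,
#' while the timescales carry independent (temporal) information and need
#' not.
#'
#' @param map A `correlation_map`.
#' @param significant_only Restrict to significant cells.
#' @return List with `table` and the two rank correlations
#'   (`cor_strength`, `cor_timescale`).
#' @export
peak_vs_pearson <- function(map, significant_only = FALSE) {
  cl <- map$cells[map$cells$status == "ok", ]
  if (significant_only) cl <- cl[cl$significant %in% TRUE, ]
  tb <- data.frame(i = cl$i, j = cl$j,
                   F_max = abs(cl$F_best),
                   tau_ns = ifelse(cl$direction == "i->j", cl$tau_fwd, cl$tau_rev),
                   abs_pearson = abs(cl$pearson))
  rank_cor <- function(a, b) {
    if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = "spearman")
  }
  cs <- rank_cor(tb$F_max, tb$abs_pearson)
  ct <- rank_cor(tb$tau_ns, tb$abs_pearson)
  list(table = tb, cor_strength = cs, cor_timescale = ct)
}

#' Export a correlation map or path as TSV
#'
#' `write_map_tsv` writes the cell (edge) list; `write_map_matrix` the square
#' signed-strength matrix (positive = direction i to j); `write_path_tsv` the
#' ordered path.
#'
#' @param map A `correlation_map`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(map$cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
write_map_matrix <- function(map, path) {
  utils::write.table(as.matrix(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @param p A `tdcf_path`.
#' @export
write_path_tsv <- function(p, path) {
  utils::write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
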