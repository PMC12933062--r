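#' Per-cell cross-session remapping statistics
#'
#' For cells with stable tuning in two environments, computes the tuning-map
#' correlation and centre-of-mass shift for A vs A' (re-exposure) and A vs B
#' (different arena), together with random controls that pair each cell's A
#' map with a random other cell's A (or B) map.
#'
#' @param maps_a,maps_b,maps_a2 Lists of `tuning_map` objects for the same
#'   cells (same order) in environments A, B and A'.
#' @param n_ctrl Number of random-pairing control iterations.
#' @param seed Optional integer seed.
#' @return A list: `cells` (`data.frame` with `cell`, `r_aa2`, `r_ab`,
#'   `com_shift_aa2`, `com_shift_ab`), `controls` (`data.frame` with pooled
#'   control values `r_a_rand_a`, `r_a_rand_b`, `com_a_rand_a`,
#'   `com_a_rand_b`).
#' @export
cross_session_cell_stats <- function(maps_a, maps_b, maps_a2, n_ctrl = 100,
                                     seed = NULL) {
  n <- length(maps_a)
  if (n == 0L)
    return(list(cells = data.frame(), controls = data.frame()))
  stopifnot(length(maps_b) == n, length(maps_a2) == n)
  com_a <- t(vapply(maps_a, map_com, numeric(2)))
  com_b <- t(vapply(maps_b, map_com, numeric(2)))
  com_a2 <- t(vapply(maps_a2, map_com, numeric(2)))
  cells <- data.frame(
    cell = seq_len(n),
    r_aa2 = vapply(seq_len(n), function(i)
      map_correlation(maps_a[[i]], maps_a2[[i]]), numeric(1)),
    r_ab = vapply(seq_len(n), function(i)
      map_correlation(maps_a[[i]], maps_b[[i]]), numeric(1)),
    com_shift_aa2 = sqrt(rowSums((com_a - com_a2)^2)),
    com_shift_ab = sqrt(rowSums((com_a - com_b)^2))
  )
  with_seed_if(seed, {
    ctrl <- lapply(seq_len(n_ctrl), function(it) {
      perm <- sample.int(n)
      # avoid self-pairing where possible
      fix <- which(perm == seq_len(n))
      if (length(fix) > 1L) perm[fix] <- perm[rev(fix)]
      data.frame(
        r_a_rand_a = vapply(seq_len(n), function(i)
          map_correlation(maps_a[[i]], maps_a[[perm[i]]]), numeric(1)),
        r_a_rand_b = vapply(seq_len(n), function(i)
          map_correlation(maps_a[[i]], maps_b[[perm[i]]]), numeric(1)),
        com_a_rand_a = sqrt(rowSums((com_a - com_a[perm, , drop = FALSE])^2)),
        com_a_rand_b = sqrt(rowSums((com_a - com_b[perm, , drop = FALSE])^2))
      )
    })
    list(cells = cells, controls = do.call(rbind, ctrl))
  })
}

#' Rotation control for remapping
#'
#' Correlates map A with each right-angle rotation of map B. Genuine global
#' remapping stays near control level for every rotation; a mere rotation of
#' the arena would produce a high correlation at one of them.
#'
#' @param map_a,map_b `tuning_map` objects on the same square grid.
#' @return A list: `r` (named vector for 0, 90, 180, 270 degrees),
#'   `best_rotation` (degrees at the argmax), `best_r`.
#' @export
rotation_control <- function(map_a, map_b) {
  a <- map_a$rate
  b <- map_b$rate
  if (nrow(a) != ncol(a) || !all(dim(a) == dim(b)))
    stop("rotation control requires square maps of equal size")
  # inverse rotation, so the reported angle is the rotation taking A to B
  unrot <- function(m) t(m[nrow(m):1, , drop = FALSE])
  rots <- list(`0` = b, `90` = unrot(b), `180` = unrot(unrot(b)),
               `270` = unrot(unrot(unrot(b))))
  r <- vapply(rots, function(m) map_correlation(a, m), numeric(1))
  best <- which.max(r)
  list(r = r, best_rotation = as.numeric(names(r)[best]), best_r = r[[best]])
}

#' Pairwise place-field distance differences across environments
#'
#' For every unordered pair of cells with a main field in each session,
#' computes the signed change in pairwise field distance between sessions:
#' `dd = d_env1(i,j) - d_env2(i,j)`. Under preserved maps (A vs A') the
#' differences concentrate at zero; under global remapping (A vs B) they are
#' as dispersed as the shuffled control (A vs A' with cell identities
#' shuffled). The three groups are compared with the Brown-Forsythe
#' (median-centred Levene) variance test.
#'
#' @param fields_a,fields_b,fields_a2 n x 2 matrices of main-field centroids
#'   (cm) for the same cells in A, B, A'.
#' @param seed Optional integer seed (for the identity shuffle).
#' @return A list: `dd_aa2`, `dd_ab`, `dd_a_rand` (signed per-pair
#'   differences), and `levene` (`data.frame` with `F`, `df1`, `df2`, `p`).
#' @export
pairwise_distance_difference <- function(fields_a, fields_b, fields_a2,
                                         seed = NULL) {
  n <- nrow(fields_a)
  if (n < 2L) stop("need at least 2 cells with fields in every session")
  da <- as.matrix(stats::dist(fields_a))
  db <- as.matrix(stats::dist(fields_b))
  da2 <- as.matrix(stats::dist(fields_a2))
  ut <- upper.tri(da)
  with_seed_if(seed, {
    perm <- sample.int(n)
    drand <- as.matrix(stats::dist(fields_a2[perm, , drop = FALSE]))
    dd_aa2 <- da[ut] - da2[ut]
    dd_ab <- da[ut] - db[ut]
    dd_rand <- da[ut] - drand[ut]
    if (length(dd_aa2) < 2L) stop("need at least 2 pairs per group")
    g <- factor(rep(c("A-A2", "A-B", "A-RandomA2"),
                    each = length(dd_aa2)))
    lv <- car::leveneTest(c(dd_aa2, dd_ab, dd_rand), g, center = stats::median)
    list(dd_aa2 = dd_aa2, dd_ab = dd_ab, dd_a_rand = dd_rand,
         levene = data.frame(F = lv$`F value`[1], df1 = lv$Df[1],
                             df2 = lv$Df[2], p = lv$`Pr(>F)`[1]))
  })
}

#' Remapping change versus anatomy
#'
#' Tests whether pairs of anatomically close place cells preserve their
#' relative field positions across environments: mutual information between
#' pairwise anatomical distance and `|dd|` (absolute change in field
#' distance), plus an expanding-circle profile of `|dd|` over anatomical
#' radii.
#'
#' @param centroids n x 2 anatomical centroids (um) of the analysed cells.
#' @param fields_env1,fields_env2 n x 2 main-field centroids (cm).
#' @param radii Anatomical radii (um) for the profile.
#' @param n_boot,n_ctrl,level Profile parameters.
#' @param seed Optional integer seed.
#' @return A list: `mi` (KSG estimate), `profile`
#'   (a `neighborhood_profile`), `pairs` (`data.frame` with `anat_dist`,
#'   `abs_dd`).
#' @export
remap_vs_anatomy <- function(centroids, fields_env1, fields_env2,
                             radii = seq(15, 60, by = 5), n_boot = 10000,
                             n_ctrl = 200, level = 0.99, seed = NULL) {
  d1 <- as.matrix(stats::dist(fields_env1))
  d2 <- as.matrix(stats::dist(fields_env2))
  anat <- as.matrix(stats::dist(centroids))
  abs_dd <- abs(d1 - d2)
  ut <- upper.tri(anat)
  mi <- mutual_information_knn(anat[ut], abs_dd[ut], seed = seed)
  prof <- expanding_circle_profile(anat, abs_dd, radii, n_boot = n_boot,
                                   n_ctrl = n_ctrl, level = level,
                                   seed = seed)
  list(mi = mi, profile = prof,
       pairs = data.frame(anat_dist = anat[ut], abs_dd = abs_dd[ut]))
}
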