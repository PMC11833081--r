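# Contact mesh construction, distance features, PCA and the free-energy
# landscape.

test_that("mesh takes the smaller chain whole and strides the larger", {
  # chain A: 25 heavy atoms; chain B: 10 heavy atoms -> m = 10, stride 2
  top <- make_topology(rep("C", 35), chains = rep(c("A", "B"), c(25, 10)),
                       residues = c(1:25, 1:10),
                       names = rep("CA", 35))
  mesh <- build_contact_mesh(top, "A", "B")
  expect_equal(length(mesh$mesh_b), 10L)
  expect_equal(mesh$mesh_b, 26:35)
  expect_equal(mesh$mesh_a, seq(1L, 19L, by = 2L))  # ordinals 1,3,...,19
  expect_equal(nrow(mesh$pair_list), 100L)

  # equal sizes: stride 1, both chains complete
  top2 <- make_topology(rep("C", 8), chains = rep(c("A", "B"), each = 4),
                        residues = c(1:4, 1:4), names = rep("CA", 8))
  mesh2 <- build_contact_mesh(top2, "A", "B")
  expect_equal(mesh2$mesh_a, 1:4)
  expect_equal(mesh2$mesh_b, 5:8)

  # cap: seeded, unique, reproducible
  m3a <- build_contact_mesh(top, "A", "B", cap = 50, seed = 99)
  m3b <- build_contact_mesh(top, "A", "B", cap = 50, seed = 99)
  expect_equal(nrow(m3a$pair_list), 50L)
  expect_false(any(duplicated(m3a$pair_list)))
  expect_identical(m3a$pair_list, m3b$pair_list)
  expect_error(build_contact_mesh(top, "A", "Z"), "no heavy atoms")
})

test_that("features are per-pair Euclidean distances on kept frames", {
  top <- make_topology(rep("C", 4), chains = c("A", "A", "B", "B"),
                       residues = c(1, 2, 1, 2), names = rep("CA", 4))
  xyz1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 4, 0), c(0, 0, 2))
  xyz2 <- xyz1 + 5
  ens <- make_ensemble(top, list(xyz1, xyz2))
  mesh <- build_contact_mesh(top, "A", "B")
  filt <- structure(list(keep = c(TRUE, FALSE), rule = "t", n_kept = 1L),
                    class = "FrameFilter")
  fe <- compute_features(ens, mesh, filt)
  expect_equal(dim(fe$values), c(1L, 4L))
  pair_of <- function(a, b) which(mesh$mesh_a[mesh$pair_list[, "a"]] == a &
                                    mesh$mesh_b[mesh$pair_list[, "b"]] == b)
  expect_equal(fe$values[1, pair_of(1, 3)], 5)

  # random probes against an independent recomputation
  set.seed(12)
  b <- generate_binding_ensemble(synthetic_spec(n_frames = 15, seed = 2))
  mesh_b <- build_contact_mesh(b$ensemble$topology, "E", "I")
  fe_b <- compute_features(b$ensemble, mesh_b)
  for (probe in 1:10) {
    f <- sample(15, 1); p <- sample(nrow(mesh_b$pair_list), 1)
    ai <- mesh_b$mesh_a[mesh_b$pair_list[p, "a"]]
    bi <- mesh_b$mesh_b[mesh_b$pair_list[p, "b"]]
    expect_equal(fe_b$values[f, p],
                 sqrt(sum((b$ensemble$coords[ai, , f] -
                             b$ensemble$coords[bi, , f])^2)))
  }
  expect_error(compute_features(ens, mesh, structure(
    list(keep = c(FALSE, FALSE), rule = "t", n_kept = 0L),
    class = "FrameFilter")), "zero frames")
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(42)
  x <- matrix(rnorm(120), nrow = 20, ncol = 6) %*% diag(c(3, 2, 1.5, 1, .5, .2))
  pca <- fit_pca(x, n_components = 6)
  eig <- eigen(cov(x), symmetric = TRUE)
  for (j in 1:6) {
    v <- eig$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v  # package sign convention
    expect_equal(unname(pca$components[, j]), v, tolerance = 1e-8)
    expect_equal(unname(pca$explained_variance[j]), eig$values[j],
                 tolerance = 1e-8)
  }
  expect_equal(sum(pca$explained_variance), sum(diag(cov(x))),
               tolerance = 1e-6 * sum(diag(cov(x))))
  # orthonormality
  expect_equal(crossprod(pca$components), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full-rank reconstruction of the centred matrix
  centred <- scale(x, center = TRUE, scale = FALSE)
  recon <- pca$scores %*% t(pca$components)
  expect_lt(max(abs(recon - centred)) / max(abs(centred)), 1e-6)
})

test_that("PCA handles rank-1 data, centring and zero-variance columns", {
  x <- cbind(1:10, 2 * (1:10))
  pca <- fit_pca(x, n_components = 1)
  expect_equal(pca$explained_variance[1] / sum(pca$explained_variance), 1)
  # the mean row scores at the origin
  xm <- rbind(colMeans(x), x)
  pca2 <- fit_pca(xm, n_components = 1)
  expect_equal(unname(pca2$scores[1, ]), 0, tolerance = 1e-12)
  # zero-variance columns are dropped and recorded
  x3 <- cbind(x, 7)
  pca3 <- fit_pca(x3, n_components = 1)
  expect_equal(unname(pca3$dropped_columns), 3L)
  expect_error(fit_pca(x[1, , drop = FALSE]), "at least 2")
})

test_that("Boltzmann inversion: modal bin at zero, ln-2 rule, exact inverse", {
  # three distinct bin locations with counts 2:1:1 -> max P = 0.5
  scores <- rbind(c(0, 0), c(0, 0), c(10, 0), c(0, 10))
  ls <- free_energy_landscape(scores, bins = 5, temperature = 300)
  occupied <- !ls$empty_mask
  expect_equal(min(ls$delta_g[occupied]), 0)
  expect_equal(sum(ls$probability), 1)
  rt <- GAS_CONSTANT_KJ * 300
  half <- ls$delta_g[occupied][ls$probability[occupied] == 0.25]
  expect_equal(unique(half), rt * log(2), tolerance = 1e-12)
  expect_equal(unique(half), 1.7288, tolerance = 2e-4)
  # inverse transform reproduces P exactly on occupied bins
  p_back <- exp(-ls$delta_g[occupied] / rt)
  p_back <- p_back / sum(p_back)
  expect_equal(p_back, ls$probability[occupied], tolerance = 1e-12)
})

test_that("degenerate and invalid landscapes are handled", {
  scores <- matrix(rep(c(1, 2), each = 4), ncol = 2)
  ls <- free_energy_landscape(scores, bins = 4)
  expect_equal(sum(!ls$empty_mask), 1L)
  expect_equal(ls$delta_g[!ls$empty_mask], 0)
  expect_true(all(is.na(ls$delta_g[ls$empty_mask])))
  expect_error(free_energy_landscape(cbind(1, NaN)), "finite")
  expect_error(free_energy_landscape(matrix(1:8, ncol = 2), bins = 1), "bins")
})

test_that("larger planted basin has lower free energy", {
  set.seed(31)
  for (ratio in c(2, 4)) {
    n2 <- 100; n1 <- ratio * n2
    scores <- rbind(cbind(rnorm(n1, 0, .5), rnorm(n1, 0, .5)),
                    cbind(rnorm(n2, 10, .5), rnorm(n2, 10, .5)))
    ls <- free_energy_landscape(scores, bins = 30)
    centers1 <- ls$edges_pc1[-1] - diff(ls$edges_pc1) / 2
    centers2 <- ls$edges_pc2[-1] - diff(ls$edges_pc2) / 2
    basin <- outer(centers1 < 5, centers2 < 5, "&")
    g_big <- min(ls$delta_g[basin & !ls$empty_mask])
    g_small <- min(ls$delta_g[!basin & !ls$empty_mask])
    expect_lt(g_big, g_small)
  }
})

test_that("cluster summaries aggregate member distances", {
  mk_trace <- function(values) {
    structure(list(values = values, frame_ids = seq_along(values),
                   group_a_label = "a", group_b_label = "b"),
              class = "DistanceTrace")
  }
  cl <- structure(list(
    labels = c(1L, 1L, 2L, 2L, 2L, -1L),
    clusters = data.frame(cluster_id = 1:2, size = c(2L, 3L),
                          representative = c(1L, 3L)),
    members = list(1:2, 3:5)), class = "ClusterResult")
  tr <- mk_trace(c(17, 18, 10, 12, 14, 99))
  s <- cluster_state_summary(cl, tr, threshold = 16.5)
  expect_equal(s$mean_distance, c(17.5, 12))
  expect_equal(s$sd_distance, c(sd(c(17, 18)), sd(c(10, 12, 14))))
  expect_equal(s$open_fraction, c(1, 0))
  expect_equal(sum(s$n), sum(cl$labels != -1L))
  expect_error(cluster_state_summary(cl, mk_trace(1:3), 16.5), "different")
})
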