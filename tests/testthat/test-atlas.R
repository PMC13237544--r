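test_that("identical maps give zero SD and collapsed CI bounds", {
  m <- small_cyl()
  nv <- nrow(m$vertices)
  maps <- rep(list(rep(2, nv)), 3)
  at <- build_scalar_atlas(list(m, m, m), maps)
  expect_equal(at$sd, rep(0, nv))
  expect_equal(at$ci_lower, at$mean)
  expect_equal(at$ci_upper, at$mean)
})

test_that("CI bounds are exactly mean plus/minus 1.96 SD", {
  m <- small_cyl()
  nv <- nrow(m$vertices)
  set.seed(4)
  maps <- lapply(1:5, function(i) rnorm(nv, 3, 1))
  at <- build_scalar_atlas(rep(list(m), 5), maps)
  expect_equal(at$ci_upper - at$mean, 1.96 * at$sd, tolerance = 1e-12)
  expect_equal(at$mean - at$ci_lower, 1.96 * at$sd, tolerance = 1e-12)
  expect_equal(at$ci_multiplier, 1.96)
})

test_that("vertexwise SD estimates the generating sigma for 20 controls", {
  m <- small_cyl()
  nv <- nrow(m$vertices)
  set.seed(7)
  maps <- lapply(1:20, function(i) rnorm(nv, 5, 0.5))
  at <- build_scalar_atlas(rep(list(m), 20), maps)
  # chi-squared sampling bounds for the SD at n = 20
  expect_gt(median(at$sd), 0.35)
  expect_lt(median(at$sd), 0.65)
  expect_equal(at$n_controls, 20L)
})

test_that("vector atlas averages unit directions", {
  m <- small_cyl()
  nv <- nrow(m$vertices)
  d <- matrix(rep(c(0, 0, 1), each = nv), nv, 3)
  va <- build_vector_atlas(list(m, m, m), list(d, 2 * d, 0.5 * d))
  expect_equal(va$mean_direction, d, tolerance = 1e-9)
  expect_equal(va$resultant_length, rep(1, nv), tolerance = 1e-9)
  # antipodal directions collapse the resultant and flag the vertex
  va2 <- build_vector_atlas(list(m, m), list(d, -d))
  expect_true(all(va2$resultant_length < 1e-6))
  expect_true(all(va2$undefined))
})

test_that("directions drawn within a 30-degree cone stay coherent", {
  # Monte-Carlo oracle: the distribution of the per-vertex resultant
  # length of 8 unit vectors uniform in a 30-degree cone
  set.seed(11)
  mk_one <- function(n) {
    u <- runif(n, cos(pi / 6), 1)
    ph <- runif(n, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    cbind(s * cos(ph), s * sin(ph), u)
  }
  sims <- replicate(2000, {
    v <- mk_one(8)
    sqrt(sum(colMeans(v)^2))
  })
  m <- small_cyl()
  nv <- nrow(m$vertices)
  va <- build_vector_atlas(rep(list(m), 8),
                           lapply(1:8, function(i) mk_one(nv)))
  expect_gt(mean(va$resultant_length), 0.9)
  expect_equal(median(va$resultant_length), median(sims),
               tolerance = 0.03)
})

test_that("projection onto the template itself reproduces the fields", {
  m <- small_cyl()
  nv <- nrow(m$vertices)
  set.seed(5)
  maps <- lapply(1:4, function(i) rnorm(nv, 4, 1))
  at <- build_scalar_atlas(rep(list(m), 4), maps)
  pr <- project_atlas(at, m)
  expect_equal(pr$mean, at$mean, tolerance = 1e-6)
  expect_equal(pr$ci_upper, at$ci_upper, tolerance = 1e-6)
  # translated patient: fields carried over within interpolation slack
  m2 <- surface_mesh(sweep(m$vertices, 2, c(3, 0, 0), "+"), m$faces)
  pr2 <- project_atlas(at, m2)
  expect_equal(pr2$mean, at$mean, tolerance = 1e-2)
  # a spatially linear field stays linear within 2%
  lin_at <- at
  lin_at$mean <- m$vertices[, 3] * 0.1
  lin_at$sd <- rep(1, nv)
  lin_at$ci_lower <- lin_at$mean - 1.96
  lin_at$ci_upper <- lin_at$mean + 1.96
  pr3 <- project_atlas(lin_at, m2)
  expect_lt(max(abs(pr3$mean - m2$vertices[, 3] * 0.1)) /
              diff(range(lin_at$mean)), 0.02)
})

test_that("scalar classification follows the strict CI rule", {
  m <- small_cyl()
  nv <- nrow(m$vertices)
  set.seed(6)
  maps <- lapply(1:6, function(i) rnorm(nv, 4, 1))
  at <- build_scalar_atlas(rep(list(m), 6), maps)
  pr <- project_atlas(at, m)
  hm <- classify_scalar(at$mean, pr)
  expect_true(all(hm$labels == "normal"))
  hm2 <- classify_scalar(at$mean + 2 * at$sd, pr)
  expect_true(all(hm2$labels[at$sd > 0] == "increased"))
  hm3 <- classify_scalar(at$mean - 2 * at$sd, pr)
  expect_true(all(hm3$labels[at$sd > 0] == "decreased"))
  # values exactly on the bound are normal
  hm4 <- classify_scalar(at$ci_upper, pr)
  expect_true(all(hm4$labels == "normal"))
})

test_that("held-out controls classify about 5% of vertices abnormal", {
  # Gaussian coverage oracle: simulate the aggregate abnormal fraction
  # for n = 20 controls, 10 held-out subjects, sample-SD CI bounds
  nv <- 300
  set.seed(9)
  sims <- replicate(200, {
    ctrl <- matrix(rnorm(20 * nv), nv, 20)
    mu <- rowMeans(ctrl)
    sdv <- apply(ctrl, 1, sd)
    held <- matrix(rnorm(10 * nv), nv, 10)
    mean(held > mu + 1.96 * sdv | held < mu - 1.96 * sdv)
  })
  lo <- quantile(sims, 0.005); hi <- quantile(sims, 0.995)
  m <- small_cyl()
  nv_m <- nrow(m$vertices)
  set.seed(10)
  maps <- lapply(1:20, function(i) rnorm(nv_m, 5, 1))
  at <- build_scalar_atlas(rep(list(m), 20), maps)
  pr <- project_atlas(at, m)
  frac <- mean(vapply(1:10, function(i) {
    hm <- classify_scalar(rnorm(nv_m, 5, 1), pr)
    mean(hm$labels != "normal")
  }, numeric(1)))
  expect_gte(frac, lo)
  expect_lte(frac, hi)
  expect_equal(frac, 0.05, tolerance = 0.6)
})

test_that("direction classification honours the 120-degree strict rule", {
  m <- small_cyl()
  nv <- nrow(m$vertices)
  base <- matrix(rep(c(1, 0, 0), each = nv), nv, 3)
  proj <- list(mean_direction = base, undefined = rep(FALSE, nv))
  rot <- function(deg) {
    th <- deg * pi / 180
    cbind(rep(cos(th), nv), rep(sin(th), nv), 0)
  }
  expect_true(all(classify_direction(-base, proj)$labels ==
                    "abnormal_direction"))                 # 180 degrees
  expect_true(all(classify_direction(rot(60), proj)$labels == "normal"))
  expect_true(all(classify_direction(rot(120), proj)$labels == "normal"))
  expect_true(all(classify_direction(rot(120.5), proj)$labels ==
                    "abnormal_direction"))
  # zero vectors and undefined atlas directions: normal-with-flag
  z <- classify_direction(base * 0, proj)
  expect_true(all(z$labels == "normal"))
  expect_true(all(z$flagged))
})

test_that("incidence proportions are exact patient-count fractions", {
  m <- small_cyl()
  nv <- nrow(m$vertices)
  mk_hm <- function(abn) {
    lab <- rep("normal", nv)
    lab[abn] <- "increased"
    structure(list(labels = factor(lab, levels = c("normal", "increased",
                                                   "decreased")),
                   flagged = rep(FALSE, nv)),
              class = "aorta_heatmap")
  }
  hms <- c(lapply(1:3, function(i) mk_hm(1:50)),
           lapply(1:7, function(i) mk_hm(integer(0))))
  im <- build_incidence_map(hms, rep(list(m), 10), class = "increased",
                            template = 1L)
  expect_equal(max(im$proportion), 0.3)
  expect_true(all(abs(im$proportion * 10 - round(im$proportion * 10)) <
                    1e-9))
  none <- build_incidence_map(hms[4:10], rep(list(m), 7),
                              class = "increased", template = 1L)
  expect_true(all(none$proportion == 0))
})

test_that("widening the CI multiplier never adds abnormal vertices", {
  m <- small_cyl()
  nv <- nrow(m$vertices)
  set.seed(12)
  maps <- lapply(1:10, function(i) rnorm(nv, 3, 1))
  patient <- rnorm(nv, 3, 2)
  counts <- vapply(c(1, 1.96, 3), function(k) {
    at <- build_scalar_atlas(rep(list(m), 10), maps, ci_multiplier = k)
    pr <- project_atlas(at, m)
    sum(classify_scalar(patient, pr)$labels != "normal")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
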