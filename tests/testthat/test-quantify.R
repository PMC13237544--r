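make_lab <- function(m, cl) label_rois(m, cl)

test_that("regional means reproduce constant and indicator maps", {
  m <- tube_mesh(radius = 10, len = 100, n_theta = 32, n_z = 50)
  cl <- straight_centerline(100)
  lab <- make_lab(m, cl)
  expect_equal(unname(roi_means(rep(7, nrow(m$vertices)), lab,
                                m$vertex_area)),
               rep(7, 4))
  ind <- as.numeric(lab == "pAAo")
  rm_ <- roi_means(ind, lab, m$vertex_area)
  expect_equal(unname(rm_), c(1, 0, 0, 0))
})

test_that("a linear-in-arclength map averages to the mid-band value", {
  m <- tube_mesh(radius = 10, len = 100, n_theta = 32, n_z = 80)
  st <- c(annulus = 0, PA_bifurcation = 25, brachiocephalic = 50,
          left_subclavian = 50, diaphragm = 100)
  cl <- straight_centerline(100, stations = st)
  lab <- make_lab(m, cl)
  vals <- m$vertices[, 3]            # f(s) = s on a straight tube
  rm_ <- roi_means(vals, lab, m$vertex_area)
  expect_equal(rm_[["pAAo"]], 12.5, tolerance = 0.02 * 100 / 12.5)
  expect_equal(rm_[["dAAo"]], 37.5, tolerance = 0.02 * 100 / 37.5)
})

test_that("empty regions yield NA with a warning, not zero", {
  m <- tube_mesh(radius = 8, len = 30, n_theta = 16, n_z = 10)
  cl <- straight_centerline(30)
  lab <- make_lab(m, cl)
  flag <- lab == "pAAo"              # flag away an entire region
  expect_warning(rm_ <- roi_means(rep(1, nrow(m$vertices)), lab,
                                  m$vertex_area, flagged = flag),
                 "pAAo")
  expect_true(is.na(rm_[["pAAo"]]))
  expect_equal(rm_[["dAAo"]], 1)
})

test_that("abnormal-area percentages are area-weighted and exact at the
           extremes", {
  m <- tube_mesh(radius = 10, len = 100, n_theta = 32, n_z = 50)
  cl <- straight_centerline(100)
  lab <- make_lab(m, cl)
  nv <- nrow(m$vertices)
  mk_hm <- function(idx, what = "increased") {
    l <- rep("normal", nv); l[idx] <- what
    structure(list(labels = factor(l, levels = c("normal", "increased",
                                                 "decreased")),
                   flagged = rep(FALSE, nv)), class = "aorta_heatmap")
  }
  all_in <- mk_hm(which(lab == "pAAo"))
  s <- abnormal_area_percent(all_in, lab, m$vertex_area)
  expect_equal(s$area_percent[s$roi == "pAAo" & s$class == "increased"],
               100)
  expect_true(s$any_abnormal_vertex[s$roi == "pAAo" &
                                      s$class == "increased"])
  none <- abnormal_area_percent(mk_hm(integer(0)), lab, m$vertex_area)
  expect_true(all(none$area_percent == 0))
  expect_false(any(none$any_abnormal_vertex))
})

test_that("a half-circumference band reads 50% of its region's area", {
  m <- tube_mesh(radius = 10, len = 100, n_theta = 48, n_z = 60)
  cl <- straight_centerline(100)
  lab <- make_lab(m, cl)
  nv <- nrow(m$vertices)
  half <- which(lab == "dAAo" & m$vertices[, 1] > 0)
  l <- rep("normal", nv); l[half] <- "increased"
  hm <- structure(list(labels = factor(l, levels = c("normal", "increased",
                                                     "decreased")),
                       flagged = rep(FALSE, nv)), class = "aorta_heatmap")
  s <- abnormal_area_percent(hm, lab, m$vertex_area)
  expect_equal(s$area_percent[s$roi == "dAAo" & s$class == "increased"],
               50, tolerance = 3 / 50)
  # class areas plus normal area account for the whole region, exactly
  roi_area <- sum(m$vertex_area[lab == "dAAo"])
  inc_area <- sum(m$vertex_area[lab == "dAAo" & hm$labels == "increased"])
  nrm_area <- sum(m$vertex_area[lab == "dAAo" & hm$labels == "normal"])
  expect_equal(inc_area + nrm_area, roi_area, tolerance = 1e-9)
})

test_that("diameter adjustment applies the stated unit conversions", {
  reg <- list(displacement = c(pAAo = 10, dAAo = 4, pDAo = 2, dDAo = 1.5),
              velocity = c(pAAo = 80, dAAo = 60, pDAo = 70, dDAo = 75),
              wss = c(pAAo = 0.8, dAAo = 0.6, pDAo = 1.0, dDAo = 0.9))
  dia <- c(root = 20, ascending = 25, desc_proximal = 20, diaphragm = 18)
  adj <- diameter_adjust(reg, dia)
  expect_equal(adj$displacement_adj[["pAAo"]], 10 / 20 * 100)  # 50
  expect_equal(adj$wss_adj[["dAAo"]], 0.6 * 1000 / 25)
  expect_equal(adj$velocity_adj[["pDAo"]], 70 / 20)
  dia2 <- dia; dia2[["ascending"]] <- NA
  adj2 <- diameter_adjust(reg, dia2)
  expect_true(is.na(adj2$displacement_adj[["dAAo"]]))
  expect_false(is.na(adj2$displacement_adj[["pAAo"]]))
  # WSS 0.8 Pa at 25 mm -> 32 mPa/mm
  expect_equal(diameter_adjust(list(wss = c(pAAo = 0.8, dAAo = NA,
                                            pDAo = NA, dDAo = NA)),
                               c(root = 25, ascending = NA,
                                 desc_proximal = NA,
                                 diaphragm = NA))$wss_adj[["pAAo"]], 32)
})

test_that("the registration audit reports paired differences and CI", {
  pre <- c(1, 2, 3, 4, 5)
  aud <- registration_audit(pre, pre)
  expect_equal(aud$mean_difference, 0)
  expect_true(aud$degenerate)
  aud2 <- registration_audit(pre, pre + 0.1)
  expect_equal(aud2$mean_difference, 0.1, tolerance = 1e-12)
  expect_equal(diff(aud2$ci), 0, tolerance = 1e-12)
  expect_true(aud2$degenerate)
  # t-CI covers zero in about 95% of null draws
  set.seed(13)
  cover <- mean(replicate(500, {
    d <- rnorm(30, 0, 0.5)
    a <- registration_audit(rep(0, 30), d)
    a$ci[1] <= 0 && 0 <= a$ci[2]
  }))
  expect_gt(cover, 0.92)
  expect_lt(cover, 0.98)
})
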