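# Colocalization and subpopulation assignment

test_that("categorize maps positivity to the seven labels", {
  expect_equal(categorize(TRUE, TRUE, TRUE), "sEV CFSE+CD63+")
  expect_equal(categorize(FALSE, FALSE, TRUE), "NP CFSE-CD63+")
  expect_equal(categorize(TRUE, FALSE, FALSE), "sEV CFSE-CD63-")
  expect_equal(categorize(FALSE, TRUE, FALSE), "NP CFSE+CD63-")
  # all seven admissible combinations give the seven distinct labels
  combos <- expand.grid(coe = c(TRUE, FALSE), cfse = c(TRUE, FALSE),
                        cd63 = c(TRUE, FALSE))
  combos <- combos[rowSums(combos) > 0, ]
  labs <- categorize(combos$coe, combos$cfse, combos$cd63)
  expect_setequal(labs, subpop_labels())
  expect_error(categorize(FALSE, FALSE, FALSE), "all-negative")
})

test_that("perfectly colocalized and single-channel particles are resolved", {
  dims <- c(120L, 120L)
  mk <- function(xy, intensity) {
    img <- render_spots_oracle(xy, intensity, dims)
    img + 0
  }
  # particle A in all three channels at (40, 40); particle B only CFSE (80, 80)
  chans <- list(
    COE = mk(rbind(c(40, 40)), 8000),
    CFSE = mk(rbind(c(40, 40), c(80, 80)), c(7000, 7000)),
    CD63 = mk(rbind(c(40, 40)), 9000))
  set.seed(20)
  chans <- lapply(chans, function(ch)
    pmax(ch + matrix(rnorm(prod(dims), 0, 5), dims[1], dims[2]), 0))
  field <- field_image(chans, 0.25, "fix")
  parts <- quiet(composite_detect(field))
  parts <- parts[order(parts$x_px), ]
  expect_equal(nrow(parts), 2L)
  expect_true(parts$pos_COE[1] && parts$pos_CFSE[1] && parts$pos_CD63[1])
  expect_equal(parts$label[1], "sEV CFSE+CD63+")
  expect_false(parts$pos_COE[2] || parts$pos_CD63[2])
  expect_true(parts$pos_CFSE[2])
  expect_equal(parts$label[2], "NP CFSE+CD63-")
  expect_equal(parts$intensity_COE[2], 0)
})

test_that("labels are invariant to channel ordering", {
  f1 <- std_pre
  f2 <- field_image(f1$channels[c("CD63", "COE", "CFSE")],
                    f1$pixel_size_um, f1$field_id)
  p1 <- quiet(composite_detect(f1))
  p2 <- quiet(composite_detect(f2))
  o1 <- order(p1$x_px, p1$y_px); o2 <- order(p2$x_px, p2$y_px)
  expect_equal(p1$label[o1], p2$label[o2])
  expect_equal(p1$x_px[o1], p2$x_px[o2])
})

test_that("7-way label accuracy exceeds 95% on a known mixture", {
  hits <- 0; total <- 0
  for (s in 1:4) {
    p <- scene_params(field_size_px = c(300L, 300L),
                      particle_density_per_um2 = 0.04, seed = 400 + s)
    sc <- quiet(generate_scene(p))
    pre <- preprocess_field(sc$field)
    parts <- quiet(composite_detect(pre))
    m <- detection_metrics(parts, sc$truth, c(300, 300))
    hits <- hits + sum(parts$label[m$matches$spot] ==
                         sc$truth$category[m$matches$truth])
    total <- total + nrow(m$matches)
  }
  expect_gte(total, 700)
  expect_gte(hits / total, 0.95)
})

test_that("greedy matching agrees with a brute-force oracle", {
  # independent oracle: repeatedly take the global minimum of the full
  # distance matrix
  oracle_match <- function(a, b, maxd) {
    d <- sqrt(outer(a$x_px, b$x_px, "-")^2 + outer(a$y_px, b$y_px, "-")^2)
    d[d > maxd] <- Inf
    pairs <- NULL
    while (any(is.finite(d))) {
      w <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
      pairs <- rbind(pairs, w)
      d[w[1], ] <- Inf; d[, w[2]] <- Inf
    }
    pairs[order(pairs[, 1]), , drop = FALSE]
  }
  mkspots <- function(n, seed) {
    set.seed(seed)
    data.frame(field_id = "f", channel = "c", spot_id = seq_len(n),
               x_px = runif(n, 0, 120), y_px = runif(n, 0, 120),
               area_px = 5L, intensity_adu = runif(n, 1000, 9000),
               background_adu = 0, circularity = 1,
               flag_edge = FALSE, flag_string = FALSE,
               flag_aggregate = FALSE)
  }
  for (seed in c(31, 32, 33)) {
    a <- mkspots(250, seed)
    b <- mkspots(250, seed + 100)
    parts <- match_spots(list(COE = a, CFSE = b), max_dist_px = 2)
    got_pairs <- sum(parts$pos_COE & parts$pos_CFSE)
    want <- oracle_match(a, b, 2)
    expect_equal(got_pairs, nrow(want))
    expect_equal(nrow(parts), 500 - nrow(want))
    # matched pairs carry both intensities
    two <- parts[parts$pos_COE & parts$pos_CFSE, ]
    expect_true(all(two$intensity_COE > 0 & two$intensity_CFSE > 0))
  }
})

test_that("match mode resolves trivial coincidence and separation", {
  sp <- function(x, y) data.frame(
    field_id = "f", channel = "c", spot_id = 1L, x_px = x, y_px = y,
    area_px = 5L, intensity_adu = 100, background_adu = 0, circularity = 1,
    flag_edge = FALSE, flag_string = FALSE, flag_aggregate = FALSE)
  same <- match_spots(list(COE = sp(10, 10), CFSE = sp(10, 10)))
  expect_equal(nrow(same), 1L)
  expect_true(same$pos_COE & same$pos_CFSE)
  apart <- match_spots(list(COE = sp(10, 10), CFSE = sp(15, 10)))
  expect_equal(nrow(apart), 2L)
})

test_that("composite and matching modes agree on well-separated fields", {
  p <- scene_params(field_size_px = c(300L, 300L),
                    particle_density_per_um2 = 0.02, seed = 55)
  sc <- quiet(generate_scene(p))
  pre <- preprocess_field(sc$field)
  pc <- quiet(composite_detect(pre))
  spots_by <- lapply(names(pre$channels), function(ch) {
    detect_one_channel(pre$channels[[ch]])
  })
  names(spots_by) <- names(pre$channels)
  pm <- match_spots(spots_by, 2)
  # compare labels particle-by-particle through position matching
  d <- sqrt(outer(pc$x_px, pm$x_px, "-")^2 + outer(pc$y_px, pm$y_px, "-")^2)
  nn <- apply(d, 1, which.min)
  ok <- d[cbind(seq_len(nrow(pc)), nn)] < 1
  agree <- pc$label[ok] == pm$label[nn[ok]]
  expect_gte(mean(ok), 0.9)
  expect_gte(mean(agree), 0.95)
})

test_that("venn fractions: point mass, additivity and the ROI identity", {
  pt <- particles_from_truth(std_scene$truth)
  # point mass
  one <- pt[pt$label == "sEV CFSE+CD63+", ]
  v1 <- venn_fractions(one)
  expect_equal(v1$fraction[v1$label == "sEV CFSE+CD63+"], 1)
  expect_equal(sum(v1$fraction), 1)
  # split into 4 pseudo-ROIs; pooled fractions must equal the
  # particle-weighted mean of per-ROI fractions exactly
  pt <- pt[!pt$flag_edge & !pt$flag_aggregate, ]
  pt$field_id <- rep(paste0("roi", 1:4), length.out = nrow(pt))
  v <- venn_fractions(pt)
  expect_equal(sum(v$fraction), 1, tolerance = 1e-9)
  per_roi <- attr(v, "per_roi")
  n_roi <- vapply(paste0("roi", 1:4), function(r)
    sum(pt$field_id == r), numeric(1))
  weighted <- as.numeric(per_roi %*% n_roi / sum(n_roi))
  expect_equal(v$fraction, weighted, tolerance = 1e-12)
  # total sEV fraction is the sum of the four vesicular labels
  sev <- sum(v$fraction[grepl("^sEV", v$label)])
  expect_equal(sev, sum(grepl("^sEV", pt$label)) / nrow(pt))
})

test_that("venn fractions recover generator probabilities within 3 SE", {
  probs <- c(0.20, 0.15, 0.10, 0.15, 0.15, 0.15, 0.10)
  parts <- NULL
  for (r in 1:10) {
    p <- scene_params(field_size_px = c(566L, 566L),
                      particle_density_per_um2 = 0.1,
                      category_probs = probs, seed = 700 + r)
    sc <- quiet(generate_scene(p))
    pr <- particles_from_truth(sc$truth, field_id = paste0("roi", r))
    parts <- rbind(parts, pr)
  }
  n <- sum(!parts$flag_edge)
  expect_gte(n, 10 * 1800)
  v <- venn_fractions(parts)
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(v$fraction - probs) < 3 * se))
})
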