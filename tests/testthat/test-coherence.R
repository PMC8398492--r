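test_that("Morlet CWT localizes a pure tone at the right scale and is linear", {
  t <- (0:144) * 2
  x <- sin(2 * pi * t / 40)
  cw <- cwt_morlet(x, 2)
  # scale-sweep oracle: |CWT| at mid-series is maximal at the scale whose
  # Fourier period is nearest 40 s
  mid <- Mod(cw$coefficients[, 73])
  expect_equal(which.max(mid), which.min(abs(cw$periods - 40)))
  # period = scale * 4*pi/(omega0 + sqrt(2 + omega0^2)) on every scale
  expect_equal(cw$periods / cw$scales,
               rep(morlet_fourier_factor(6), length(cw$scales)),
               tolerance = 1e-12)
  # zero signal -> zero coefficients; linearity
  cw0 <- cwt_morlet(rep(0, 145), 2)
  expect_true(all(Mod(cw0$coefficients) == 0))
  cw2 <- cwt_morlet(2 * x, 2)
  expect_lt(max(Mod(cw2$coefficients - 2 * cw$coefficients)), 1e-10)
  # shape and COI bookkeeping
  expect_equal(dim(cw$coefficients), c(length(cw$scales), 145))
  expect_equal(cw$coi[1], 0)
  expect_equal(cw$coi, rev(cw$coi))
  expect_error(cwt_morlet(x, 2, coherence_config(period_range = c(1, 50))),
               "period_range")
})

test_that("the smoothing operator preserves constants and is linear", {
  cfg <- coherence_config()
  cw <- cwt_morlet(rnorm(145), 2, cfg)
  m <- matrix(5.5, length(cw$scales), 145)
  sm <- boldwct:::smooth_scalogram(m, cw$scales, 2, cfg)
  expect_equal(sm, m, tolerance = 1e-10)
  # commutes with global complex scaling
  set.seed(4)
  z <- matrix(complex(real = rnorm(length(cw$scales) * 145),
                      imaginary = rnorm(length(cw$scales) * 145)),
              length(cw$scales), 145)
  c0 <- 2 - 3i
  s1 <- boldwct:::smooth_scalogram(c0 * z, cw$scales, 2, cfg)
  s2 <- c0 * boldwct:::smooth_scalogram(z, cw$scales, 2, cfg)
  expect_lt(max(Mod(s1 - s2)), 1e-9)
  # interior impulse: mass confined to the kernel support and conserved
  imp <- matrix(0, length(cw$scales), 145)
  center <- ceiling(length(cw$scales) / 2)
  imp[center, 73] <- 1
  si <- boldwct:::smooth_scalogram(imp, cw$scales, 2, cfg)
  expect_equal(sum(si), 1, tolerance = 1e-6)
  expect_true(all(si[, c(1:20, 126:145)] < 1e-12))
  # grid mismatch -> error
  cw_short <- cwt_morlet(rnorm(64), 2, cfg)
  expect_error(smooth_cross_spectrum(cw, cw_short), "grids")
})

test_that("wavelet coherence is bounded, symmetric, and 1 on self-pairs", {
  set.seed(11)
  x <- rnorm(145); y <- rnorm(145)
  mxy <- wavelet_coherence(x, y, 2)
  expect_true(all(mxy$values >= 0 & mxy$values <= 1))
  self <- wavelet_coherence(x, x, 2)
  expect_lt(max(abs(self$values - 1)), 1e-6)
  myx <- wavelet_coherence(y, x, 2)
  expect_lt(max(abs(mxy$values - myx$values)), 1e-9)
  expect_error(wavelet_coherence(rep(1, 145), x, 2), "constant")
  expect_error(wavelet_coherence(x, y[1:100], 2), "equal length")
})

test_that("without smoothing the coherence ratio degenerates to exactly 1", {
  set.seed(12)
  x <- rnorm(145); y <- rnorm(145)
  raw <- wavelet_coherence(x, y, 2, smoothing = "none")
  expect_lt(max(abs(raw$values - 1)), 1e-9)
})

test_that("shared-band signals show elevated coherence inside the band", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    t <- (0:144) * 2
    shared <- sin(2 * pi * t / 40 + runif(1, 0, 2 * pi))
    x <- shared + rnorm(145) * 0.8
    y <- shared + rnorm(145) * 0.8
    m <- wavelet_coherence(x, y, 2)
    inb <- m$periods >= 30 & m$periods <= 55
    hits <- hits + (mean(m$values[inb, ]) > mean(m$values[!inb, ]))
  }
  expect_equal(hits, 20)
})

test_that("coherence maps shift with a common circular time shift (interior)", {
  set.seed(5)
  t <- (0:144) * 2
  x <- sin(2 * pi * t / 40) + rnorm(145) * 0.5
  y <- sin(2 * pi * t / 40 + 1) + rnorm(145) * 0.5
  k <- 10
  shift <- function(v) c(v[-(1:k)], v[1:k])
  m1 <- wavelet_coherence(x, y, 2)$values
  m2 <- wavelet_coherence(shift(x), shift(y), 2)$values
  interior <- 40:100
  expect_lt(max(abs(m1[, interior] - m2[, interior - k])), 0.05)
})

test_that("scalogram rendering is shape-exact, anchored and byte-deterministic", {
  set.seed(3)
  m <- wavelet_coherence(rnorm(145), rnorm(145), 2)
  img <- render_scalogram(m)
  expect_equal(dim(img$pixels), c(224, 224, 3))
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
  # constant maps hit the palette endpoints uniformly
  lo <- m; lo$values[] <- 0
  hi <- m; hi$values[] <- 1
  pal <- boldwct:::coherence_palette(m$config$colormap)
  img_lo <- render_scalogram(lo)
  img_hi <- render_scalogram(hi)
  expect_equal(unique(as.vector(img_lo$pixels[, , 1])), as.integer(pal[1, 1]))
  expect_equal(unique(as.vector(img_hi$pixels[, , 1])), as.integer(pal[256, 1]))
  # identical maps -> byte-identical rasters
  expect_identical(render_scalogram(m)$pixels, img$pixels)
  # PNG writing round-trips the raster bytes
  path <- withr::local_tempfile(fileext = ".png")
  write_scalogram_png(img, path)
  back <- round(png::readPNG(path) * 255)
  expect_equal(as.integer(back), as.integer(img$pixels))
})

test_that("pairwise scalograms cover every non-self pair with labels", {
  rec <- toy_recording(n_nodes = 6, group = "NC", site = "S2")
  cfg <- coherence_config(image_size = c(32, 32))
  imgs <- pairwise_scalograms(rec, 2, cfg)
  expect_length(imgs, 5)
  partners <- sapply(imgs, function(i) i$partner_node)
  expect_identical(sort(partners), c(1L, 3L, 4L, 5L, 6L))
  expect_true(all(sapply(imgs, function(i) i$seed_node) == 2))
  expect_true(all(sapply(imgs, function(i) i$group) == "NC"))
  expect_true(all(sapply(imgs, function(i) i$site) == "S2"))
  # two seed nodes double the count; out-of-range seed errors
  expect_length(pairwise_scalograms(rec, c(2, 4), cfg), 10)
  expect_error(pairwise_scalograms(rec, 9, cfg), "out of range")
  # cached-auto-spectrum path agrees with the direct two-signal computation
  direct <- wavelet_coherence(rec$data[, 2], rec$data[, 1], rec$tr_seconds, cfg)
  expect_identical(render_scalogram(direct, cfg)$pixels, imgs[[1]]$pixels)
})
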