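test_that("candidate-link graph equals brute-force pair enumeration", {
  # spatial and temporal bounds are respected
  one <- data.frame(frame = 1L, x_um = 0, y_um = 0)
  expect_equal(nrow(build_link_graph(one)$edges), 0L)
  two <- data.frame(frame = c(1L, 5L), x_um = c(0, 0), y_um = c(0, 0))
  expect_equal(nrow(build_link_graph(two)$edges), 0L)
  # 200 random detections over 10 frames
  set.seed(301)
  loc <- data.frame(frame = sample(1:10, 200, replace = TRUE),
                    x_um = runif(200, 0, 8), y_um = runif(200, 0, 8))
  g <- build_link_graph(loc)
  bf <- brute_force_pairs(loc)
  key <- function(d) sort(paste(d$src, d$dst, d$delta))
  expect_equal(key(g$edges), key(bf))
  expect_true(all(g$edges$dist_um <= 1.25))
  expect_true(all(g$edges$delta %in% 1:3))
})

test_that("link marginals behave sensibly and match exact enumeration", {
  # an isolated zero-displacement pair beats the no-link alternative
  loc <- data.frame(frame = 1:2, x_um = c(1, 1), y_um = c(1, 1))
  g <- infer_link_probabilities(build_link_graph(loc), dt = 0.01)
  expect_gt(g$edges$p, g$nodes$p_no_out[1])
  # a near target outranks a far target
  loc <- data.frame(frame = c(1L, 2L, 2L), x_um = c(0, 0.1, 1.0),
                    y_um = c(0, 0, 0))
  g <- infer_link_probabilities(build_link_graph(loc), dt = 0.01)
  e <- g$edges
  expect_gt(e$p[e$dst == 2], e$p[e$dst == 3])
  # small random instances against the exhaustive-enumeration oracle
  set.seed(302)
  worst <- 0
  tested <- 0L
  for (r in 1:60) {
    n <- sample(2:4, 1)
    loc <- data.frame(frame = sample(1:3, n, replace = TRUE),
                      x_um = runif(n, 0, 1.2), y_um = runif(n, 0, 1.2))
    g <- build_link_graph(loc)
    if (nrow(g$edges) == 0L) next
    g <- infer_link_probabilities(g, dt = 0.01)
    worst <- max(worst, max(abs(g$edges$p - enum_link_marginals(g))))
    tested <- tested + 1L
  }
  expect_gt(tested, 30L)
  expect_lt(worst, 0.05)
  expect_error(infer_link_probabilities(build_link_graph(one <- data.frame(
    frame = 1L, x_um = 0, y_um = 0)), dt = -1), "dt")
})

test_that("marginals satisfy the per-detection normalization invariant", {
  set.seed(303)
  loc <- data.frame(frame = sample(1:6, 40, replace = TRUE),
                    x_um = runif(40, 0, 3), y_um = runif(40, 0, 3))
  g <- infer_link_probabilities(build_link_graph(loc), dt = 0.01)
  n <- nrow(g$nodes)
  out_sum <- smtpipe:::tapply_sum(g$edges$p, g$edges$src, n)
  in_sum <- smtpipe:::tapply_sum(g$edges$p, g$edges$dst, n)
  expect_true(all(abs(g$nodes$p_no_out + out_sum - 1) < 1e-6))
  expect_true(all(abs(g$nodes$p_no_in + in_sum - 1) < 1e-6))
  expect_true(all(g$edges$p >= 0 & g$edges$p <= 1))
})

test_that("hill-climbing selection is conflict-free and globally optimal on
          small instances", {
  # empty graph
  g <- infer_link_probabilities(build_link_graph(
    data.frame(frame = 1L, x_um = 0, y_um = 0)), dt = 0.01)
  expect_length(select_links(g), 0L)
  # two sources competing for one target: the closer one wins
  loc <- data.frame(frame = c(1L, 1L, 2L), x_um = c(0, 0.6, 0.05),
                    y_um = c(0, 0, 0))
  g <- infer_link_probabilities(build_link_graph(loc), dt = 0.01)
  sel <- select_links(g)
  expect_length(sel, 1L)
  expect_equal(g$edges$src[sel], 1L)
  # exhaustive-search optimum on random instances (full candidate set)
  set.seed(304)
  fails <- 0L
  for (r in 1:60) {
    n <- sample(3:6, 1)
    loc <- data.frame(frame = sample(1:4, n, replace = TRUE),
                      x_um = runif(n, 0, 1.5), y_um = runif(n, 0, 1.5))
    g <- infer_link_probabilities(build_link_graph(loc), dt = 0.01)
    if (nrow(g$edges) == 0L) next
    sel <- select_links(g, prune_factor = 0)
    if (attr(sel, "objective") < enum_best_objective(g) - 1e-9)
      fails <- fails + 1L
  }
  expect_equal(fails, 0L)
})

test_that("trajectory assembly yields disjoint frame-ordered components", {
  # chain a -> b -> c
  loc <- data.frame(frame = 1:3, x_um = c(0, 0.05, 0.1), y_um = c(0, 0, 0))
  g <- infer_link_probabilities(build_link_graph(loc), dt = 0.01)
  tr <- assemble_trajectories(g, select_links(g), dt = 0.01)
  expect_equal(length(unique(tr$points$trajectory)), 1L)
  expect_equal(nrow(tr$jumps), 2L)
  # no links: n singletons
  loc <- data.frame(frame = c(1L, 1L, 1L), x_um = 1:3, y_um = 0)
  g <- infer_link_probabilities(build_link_graph(loc), dt = 0.01)
  tr <- assemble_trajectories(g, select_links(g), dt = 0.01)
  expect_equal(length(unique(tr$points$trajectory)), 3L)
  expect_equal(nrow(tr$jumps), 0L)
  # every localization appears exactly once
  set.seed(305)
  loc <- data.frame(frame = sample(1:8, 60, replace = TRUE),
                    x_um = runif(60, 0, 4), y_um = runif(60, 0, 4))
  g <- infer_link_probabilities(build_link_graph(loc), dt = 0.01)
  tr <- assemble_trajectories(g, select_links(g), dt = 0.01)
  expect_equal(nrow(tr$points), 60L)
  expect_false(any(duplicated(tr$points$id)))
  # frames strictly increase within each trajectory
  ok <- tapply(tr$points$frame, tr$points$trajectory,
               function(f) all(diff(f) > 0))
  expect_true(all(ok))
})

test_that("links on low-density ground truth connect the right emitters", {
  good <- 0L; total <- 0L
  for (s in 1:4) {
    cfg <- sim_config(n_frames = 60L, image_shape = c(220L, 220L),
                      seed = 8L + s, n_nuclei = 2L, emitter_density = 0.02,
                      bleach_survival = 0.95)
    sim <- simulate_fov(cfg)
    tru <- sim$truth
    loc <- data.frame(frame = tru$frame, x_um = tru$x_um, y_um = tru$y_um)
    g <- infer_link_probabilities(build_link_graph(loc),
                                  dt = cfg$frame_interval)
    e <- g$edges[select_links(g), ]
    good <- good + sum(tru$emitter[e$src] == tru$emitter[e$dst])
    total <- total + nrow(e)
  }
  expect_gt(total, 200L)
  expect_gte(good / total, 0.99)
})
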