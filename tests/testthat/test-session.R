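# Configuration files, session directories and the programmatic pipeline
# entry points behind the command-line interface.

write_yaml_config <- function(lines) {
  path <- tempfile(fileext = ".yaml")
  writeLines(lines, path)
  path
}

test_that("configuration files round-trip through parse and serialise", {
  path <- write_yaml_config(c(
    "seed: 42",
    "generator:",
    "  n_animals: 3",
    "  n_frames: 100",
    "  arena_radius: 90",
    "tracking:",
    "  n_pos: 50",
    "  n_neg: 50",
    "  max_batches: 10"))
  on.exit(unlink(path), add = TRUE)
  cfg <- read_config(path)
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$generator$n_animals, 3L)
  expect_equal(cfg$generator$arena_radius, 90)
  # n_animals propagates from the generator into the tracking config
  expect_equal(cfg$tracking$n_animals, 3L)
  expect_equal(cfg$tracking$max_batches, 10L)
  # unspecified fields take the documented defaults
  expect_equal(cfg$tracking$d_neg, 10)
  expect_equal(cfg$tracking$silhouette_stop, 0.91)
  # serialise and parse again: identical configs
  path2 <- tempfile(fileext = ".yaml")
  on.exit(unlink(path2), add = TRUE)
  yaml::write_yaml(list(seed = cfg$seed,
                        generator = unclass(cfg$generator),
                        tracking = unclass(cfg$tracking)), path2)
  cfg2 <- read_config(path2)
  expect_equal(unclass(cfg2$generator), unclass(cfg$generator))
  expect_equal(unclass(cfg2$tracking), unclass(cfg$tracking))
})

test_that("invalid configurations are rejected with the config error class", {
  expect_error(read_config(tempfile()), class = "pairtrack_invalid_config")
  bad <- write_yaml_config(c("generator:", "  n_animals: 1"))
  on.exit(unlink(bad), add = TRUE)
  expect_error(read_config(bad), class = "pairtrack_invalid_config")
  bad2 <- write_yaml_config(c("tracking:", "  mix_fraction: 2"))
  on.exit(unlink(bad2), add = TRUE)
  expect_error(read_config(bad2), class = "pairtrack_invalid_config")
  # generating without a generator section
  ok <- write_yaml_config(c("tracking:", "  n_animals: 3"))
  on.exit(unlink(ok), add = TRUE)
  expect_error(run_generate(ok, tempfile()),
               class = "pairtrack_invalid_config")
})

test_that("generate + track produce a complete, reproducible session", {
  cfgf <- write_yaml_config(c(
    "seed: 3",
    "generator:",
    "  n_animals: 3",
    "  n_frames: 150",
    "  arena_radius: 90",
    "tracking:",
    "  n_pos: 50",
    "  n_neg: 50",
    "  eval_every: 10",
    "  max_batches: 150"))
  data_dir <- tempfile("dataset")
  s1 <- tempfile("session1"); s2 <- tempfile("session2")
  on.exit(unlink(c(cfgf, data_dir, s1, s2), recursive = TRUE), add = TRUE)

  run_generate(cfgf, data_dir)
  expect_true(dir.exists(file.path(data_dir, "frames")))
  expect_true(file.exists(file.path(data_dir, "groundtruth.csv")))
  expect_length(list.files(file.path(data_dir, "frames"), pattern = "\\.png$"),
                150L)

  fit <- run_track(data_dir, s1, cfgf)
  expect_s3_class(fit, "pairtrack")
  for (f in c("config.yaml", "fragments.csv", "model.json",
              "cluster_report.json", "identities.csv", "trajectories.csv",
              "metrics.json", "log.jsonl"))
    expect_true(file.exists(file.path(s1, f)), label = f)
  metrics <- jsonlite::read_json(file.path(s1, "metrics.json"))
  expect_equal(metrics$seed, 3L)
  expect_equal(metrics$n_animals, 3L)
  expect_true(metrics$stop_reason %in% c("silhouette_reached", "max_batches"))

  # identical config and seed reproduce the session metrics exactly
  run_track(data_dir, s2, cfgf)
  expect_identical(readLines(file.path(s1, "metrics.json")),
                   readLines(file.path(s2, "metrics.json")))
  expect_identical(readLines(file.path(s1, "trajectories.csv")),
                   readLines(file.path(s2, "trajectories.csv")))

  # evaluating the session against its own ground truth yields valid scores
  ev <- run_evaluate(s1, file.path(data_dir, "groundtruth.csv"))
  expect_true(file.exists(file.path(s1, "evaluation.csv")))
  expect_gte(ev$idf1_excl, 0); expect_lte(ev$idf1_excl, 1)
  expect_gte(ev$idf1_incl, 0); expect_lte(ev$idf1_incl, 1)
})

test_that("ground truth evaluated against itself scores a perfect IDF1", {
  ds <- small_dataset()
  gt <- ground_truth_trajectories(ds)
  session <- tempfile("selftest")
  dir.create(session)
  on.exit(unlink(session, recursive = TRUE), add = TRUE)
  write_trajectories(gt, file.path(session, "trajectories.csv"))
  gtf <- file.path(session, "groundtruth.csv")
  write_trajectories(gt, gtf)
  ev <- run_evaluate(session, gtf, match_radius = 2)
  expect_equal(ev$idf1_excl, 1)
  expect_equal(ev$idf1_incl, 1)
})

test_that("evaluation demands an existing, compatible ground truth", {
  session <- tempfile("badsession")
  dir.create(session)
  on.exit(unlink(session, recursive = TRUE), add = TRUE)
  gt <- walkers(2, 10)
  write_trajectories(gt, file.path(session, "trajectories.csv"))
  expect_error(run_evaluate(session, tempfile()),
               class = "pairtrack_invalid_input")
  short <- file.path(session, "short.csv")
  write_trajectories(walkers(2, 5), short)
  expect_error(run_evaluate(session, short),
               class = "pairtrack_invalid_input")
})

test_that("a low-connectivity run warns but still completes", {
  # animals 1 and 2 coexist on frames [0,100); animal 3 appears alone on
  # [100,200): connectivity (1+1+0)/3 / 2 = 1/3, below the 0.5 threshold
  L <- 8L
  set.seed(13)
  base <- lapply(1:3, function(i) matrix(stats::runif(L * L), L, L))
  mk <- function(t, i, y) pairtrack:::new_blob(
    frame = t, centroid = c(t %% 100 + 1, y), pixel_count = 60,
    bbox = c(t %% 100 - 4, y - 4, t %% 100 + 6, y + 6),
    crop = pmin(1, pmax(0, base[[i]] + matrix(stats::rnorm(L * L, 0, 0.02), L, L))),
    kind = "individual", gt_id = i)
  blobs <- lapply(seq_len(200) - 1L, function(t) {
    if (t < 100) list(mk(t, 1L, 100), mk(t, 2L, 200)) else list(mk(t, 3L, 300))
  })
  cfg <- tracking_config(n_animals = 3, crop_size = 8, n_pos = 20, n_neg = 20,
                         eval_every = 10, max_batches = 30)
  fit <- track(blobs, n_animals = 3, config = cfg, seed = 4)
  expect_length(fit$warnings, 1L)
  expect_match(fit$warnings, "connectivity")
  expect_lt(fit$connectivity, 0.5)
  expect_equal(fit$n_global_fragments, 0L)
  # the run still assigns exclusive identities to the coexisting fragments
  ids <- fit$assignment$table$identity
  e <- fit$graph$edges
  expect_true(all(ids[e[, 1]] != ids[e[, 2]]))
})
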