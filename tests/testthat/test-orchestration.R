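test_that("model templating substitutes exact full-precision values", {
  out <- render_model("rate 'k1' __FREE__k1", c(k1 = 0.03))
  expect_identical(out, paste0("rate 'k1' ", sprintf("%.17e", 0.03)))
  # 17 significant digits round-trip the binary value exactly
  expect_identical(as.numeric(sub(".*' ", "", out)), 0.03)
  # deterministic, byte-identical re-render
  tpl <- "a __FREE__k1 b __FREE__k2 c __FREE__k1"
  out1 <- render_model(tpl, c(k1 = 1 / 3, k2 = 2e-7))
  expect_identical(out1, render_model(tpl, c(k1 = 1 / 3, k2 = 2e-7)))
  expect_false(grepl("__FREE__", out1))
  # errors name the offending parameters
  expect_error(render_model(tpl, c(k1 = 1)), "k2")
  expect_error(render_model("x __FREE__k1", c(k1 = 1, zz = 2)), "zz")
  expect_identical(scan_free_parameters(tpl), c("k1", "k2"))
  expect_identical(scan_free_parameters("no placeholders"), character(0))
})

test_that("simulator output dialects parse and reject ragged rows", {
  g <- parse_sim_table("# time A B\n0 10 0\n1 9 1\n", "gdat")
  expect_identical(names(g), c("time", "A", "B"))
  expect_identical(nrow(g), 2L)
  expect_equal(g$A, c(10, 9))

  k <- parse_sim_table("\"[T]\",\"A\"\n0,5\n1,6\n2,7\n", "kasim_csv")
  expect_identical(nrow(k), 3L)
  expect_equal(k$A, 5:7 + 0)

  t <- parse_sim_table("time\tA\n0\t1\n", "tsv")
  expect_equal(t$A, 1)

  expect_error(parse_sim_table("# time A B\n0 10\n", "gdat"), "line 2")
  expect_error(parse_sim_table("time\tA\n0\tfoo\n", "tsv"), "non-numeric")
})

test_that("dispatch preserves order, isolates failures and matches serially", {
  jobs <- lapply(1:20, function(i) {
    force(i)
    function() {
      if (i == 13) stop("bad job")
      i^2
    }
  })
  res1 <- dispatch(jobs, workers = 1)
  expect_length(res1, 20)
  expect_identical(unlist(res1[1:12]), (1:12)^2)
  expect_s3_class(res1[[13]], "dispatch_failure")
  expect_identical(res1[[20]], 400)
  res2 <- dispatch(jobs, workers = 2)
  expect_equal(res2[-13], res1[-13])
  expect_error(dispatch(jobs, workers = 1, fail_fast = TRUE), "job 13")
})

test_that("seeded SSA jobs are identical for any worker count", {
  net <- aguilera_network()
  jobs <- lapply(1:6, function(i) {
    force(i)
    function() simulate_ssa(net, seq(0, 50, 10), seed = 100 + i)
  })
  expect_identical(dispatch(jobs, workers = 1), dispatch(jobs, workers = 2))
})

test_that("the command backend renders, runs and aligns an external simulator", {
  # stand-in external simulator: a shell script that ignores the model and
  # writes a deterministic gdat table whose first value is the seed
  sim <- tempfile(fileext = ".sh")
  writeLines(c(
    "#!/bin/sh",
    "# $1 model $2 seed $3 output",
    "printf '# time A\\n0 %s\\n1 7\\n2 9\\n' \"$2\" > \"$3\""
  ), sim)
  Sys.chmod(sim, "0755")
  backend <- command_backend(
    command = paste(sim, "{model}", "{seed}", "{output}"),
    model_template = "k __FREE__k",
    dialect = "gdat"
  )
  arr <- backend(c(k = 0.5), n_sims = 2, times = c(0, 2), seed = 9)
  expect_identical(dim(arr), c(2L, 2L, 1L))
  expect_equal(arr[1, 2, 1], 9)  # aligned to t = 2, no interpolation
  expect_equal(arr[1, 1, 1], derive_seed(9, "run", 1))
  expect_error(command_backend("x {model} {seed}", "t"), "\\{output\\}")
  # missing requested time
  expect_error(backend(c(k = 1), 1, times = c(0, 5), seed = 1), "5")
})

test_that("slurm scripts enumerate one array task per job", {
  sc <- slurm_script(c("echo a", "echo b"), job_name = "jj")
  expect_match(sc, "#SBATCH --array=1-2")
  expect_match(sc, "1\\) echo a ;;")
  expect_match(sc, "2\\) echo b ;;")
})

test_that("calibration results are independent of the worker count", {
  net <- aguilera_network()
  d <- generate_synthetic_dataset(net, 3, t_grid = seq(0, 60, 20), seed = 5)
  specs <- param_specs_around(aguilera_true_rates())
  mk <- function(workers) {
    cfg <- ga_config(objectives = "SDA", pop_size = 6, elite = 2, iterations = 2,
                     n_sims = 2, seed = 17, workers = workers)
    calibrate(d, specs, cfg, builtin_backend(net))
  }
  expect_identical(mk(1)$history, mk(2)$history)
})
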