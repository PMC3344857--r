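make_stack_fixture <- function(root, n_stacks = 2L, n_scs = 3L,
                               n_points = 5L) {
  set.seed(101)
  for (s in seq_len(n_stacks)) {
    sdir <- file.path(root, sprintf("Stack%02d", s))
    dir.create(sdir, recursive = TRUE)
    for (k in seq_len(n_scs)) {
      df <- data.frame(X = round(runif(n_points, 0, 9), 4),
                       Y = round(runif(n_points, 0, 9), 4),
                       Z = round(runif(n_points, 0, 9), 4))
      write.csv(df, file.path(sdir, sprintf("SC%02d.csv", k)),
                row.names = FALSE)
    }
  }
}

test_that("stack reader parses the per-nucleus layout and validates input", {
  root <- withr::local_tempdir()
  make_stack_fixture(root)
  ds <- read_sc_stacks(root)
  expect_length(ds, 2L)
  expect_length(ds[[1L]]$traces, 3L)
  expect_equal(nrow(ds[[1L]]$traces[[1L]]$points), 5L)
  expect_equal(ds[[1L]]$source, "experimental")
  expect_equal(vapply(ds[[2L]]$traces, `[[`, "", "sc_id"),
               c("SC01", "SC02", "SC03"))

  # missing coordinate column names the offending sheet
  bad <- file.path(root, "Stack01", "SC99.csv")
  write.csv(data.frame(X = 1:3, Y = 1:3), bad, row.names = FALSE)
  expect_error(read_sc_stacks(root), "SC99.*lacks coordinate column Z")
  unlink(bad)
  # non-numeric cell is reported with its row
  write.csv(data.frame(X = c("1", "oops", "3"), Y = 1:3, Z = 1:3),
            bad, row.names = FALSE)
  expect_error(read_sc_stacks(root), "non-numeric value.*row 2")
  unlink(bad)
  # empty stacks are skipped with a warning
  dir.create(file.path(root, "StackEmpty"))
  expect_warning(ds2 <- read_sc_stacks(root), "empty")
  expect_length(ds2, 2L)
})

test_that("write_traces -> read_sc_stacks roundtrips losslessly", {
  root <- withr::local_tempdir()
  make_stack_fixture(root)
  ds <- read_sc_stacks(root)
  out <- file.path(root, "copy")
  write_traces(ds, out)
  back <- read_sc_stacks(out)
  expect_equal(names(back), names(ds))
  for (nm in names(ds))
    for (k in seq_along(ds[[nm]]$traces))
      expect_equal(back[[nm]]$traces[[k]]$points,
                   ds[[nm]]$traces[[k]]$points, tolerance = 1e-9)
  expect_error(write_traces(list(), out), "no datasets")
  # unicode SC labels survive the roundtrip
  tr <- sc_trace(matrix(1:6, ncol = 3), sc_id = "SCµ", nucleus_id = "n")
  write_traces(nucleus_dataset(list(tr), "n", source = "synthetic"),
               file.path(root, "uni"))
  uni <- read_sc_stacks(file.path(root, "uni"))
  expect_equal(uni$n$traces[[1L]]$sc_id, "SCµ")
})

test_that("nanometer-scale coordinates are auto-detected and converted", {
  root <- withr::local_tempdir()
  sdir <- file.path(root, "StackNM")
  dir.create(sdir, recursive = TRUE)
  write.csv(data.frame(X = c(0, 4000), Y = c(0, 3000), Z = c(0, 0)),
            file.path(sdir, "SC01.csv"), row.names = FALSE)
  ds <- read_sc_stacks(root)  # units = "auto"
  expect_equal(squared_end_to_end(ds$StackNM$traces[[1L]]), 25)
  ds_um <- read_sc_stacks(root, units = "um")
  expect_equal(squared_end_to_end(ds_um$StackNM$traces[[1L]]), 25e6)
})

test_that("uniform resampling preserves endpoints, spacing and arclength", {
  seg <- rbind(c(0, 0, 0), c(10, 0, 0))
  rs <- resample_uniform(seg, 6L)
  expect_equal(diff(rs[, 1L]), rep(2, 5))
  # smooth filament-like curve (jagged random walks lose arclength to
  # corner cutting; reconstructed backbones are smooth at the site scale)
  t <- seq(0, 4 * pi, length.out = 500)
  curve <- cbind(cos(t), sin(t), t / 4)
  for (n in c(10L, 30L, 200L)) {
    rs <- resample_uniform(curve, n)
    expect_equal(rs[1L, ], curve[1L, ])
    expect_equal(rs[n, ], curve[nrow(curve), ])
  }
  rs200 <- resample_uniform(curve, 200L)
  expect_equal(arclength(rs200), arclength(curve), tolerance = 0.005)
  # idempotent at matched n
  again <- resample_uniform(rs200, 200L)
  expect_lt(max(abs(again - rs200)), 1e-4)
  expect_error(resample_uniform(seg, 1L))
})

test_that("trace validation and summaries behave on degenerate shapes", {
  expect_error(sc_trace(matrix(1:3, 1L)), "at least 2")
  expect_error(sc_trace(rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
  expect_error(sc_trace(rbind(c(0, 0, 0), c(NA, 0, 0))), "finite")
  expect_error(nucleus_dataset(list(), "x"), "at least one")
  tr <- sc_trace(cbind(0:5, 0, 0), sc_id = "a")
  expect_error(nucleus_dataset(list(tr, tr), "x"), "unique")

  rod <- sc_trace(cbind(seq(0, 12, by = 2), 0, 0), "rod", "n1")
  closed <- sc_trace(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                           c(0, 1e-14, 0)), "loop", "n1")
  ds <- nucleus_dataset(list(rod, closed), "n1", source = "synthetic")
  sm <- trace_summary(ds)
  expect_equal(nrow(sm), 2L)
  expect_equal(sm$contour[1L], sm$end_to_end[1L])
  expect_lt(sm$end_to_end[2L], 1e-10)
  cfg <- synth_config(n_chains = 19L, n_points = 12L, seed = 2L)
  expect_equal(nrow(trace_summary(generate_nucleus(cfg))), 19L)
})
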