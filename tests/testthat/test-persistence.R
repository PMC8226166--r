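# a contact_series built directly from a known incidence matrix, so
# persistence arithmetic can be checked independently of any geometry
series_from_incidence <- function(inc, info, topology = NULL) {
  structure(list(per_frame_ncc = rep(0L, nrow(inc)),
                 incidence = inc, pair_info = info, cutoff = 4.0,
                 n_frames = nrow(inc), topology = topology),
            class = "contact_series")
}

pair_info_row <- function(pair, scope = "intermolecular") {
  parts <- strsplit(pair, "[-:]")[[1]]
  data.frame(pair = pair, chain_a = parts[1], res_a = as.integer(parts[2]),
             chain_b = parts[3], res_b = as.integer(parts[4]),
             scope = scope, stringsAsFactors = FALSE)
}

test_that("persistence fractions are exact frame-count ratios", {
  inc <- matrix(FALSE, 100, 2,
                dimnames = list(NULL, c("A:3-B:8", "A:2-B:9")))
  inc[1:98, 1] <- TRUE
  inc[1:64, 2] <- TRUE
  cs <- series_from_incidence(inc, rbind(pair_info_row("A:3-B:8"),
                                         pair_info_row("A:2-B:9")))
  expect_identical(persistence_fraction(cs, "A:3-B:8"), 0.98)
  expect_identical(persistence_fraction(cs, "A:2-B:9"), 0.64)
  # a pair never seen in contact has zero persistence
  expect_identical(persistence_fraction(cs, "A:1-B:1"), 0)
  # length-4 descriptors are accepted and canonicalized
  expect_identical(persistence_fraction(cs, c("B", 8, "A", 3)), 0.98)
  expect_error(persistence_fraction(cs, "A3B8"), "malformed")
})

test_that("interaction maps apply the inclusive 10% threshold", {
  inc <- matrix(FALSE, 200, 3,
                dimnames = list(NULL, c("A:2-B:3", "A:4-B:5", "A:6-B:7")))
  inc[1:20, 1] <- TRUE    # exactly 10%
  inc[1:19, 2] <- TRUE    # 9.5%
  inc[1:38, 3] <- TRUE    # 19%
  cs <- series_from_incidence(inc, rbind(pair_info_row("A:2-B:3"),
                                         pair_info_row("A:4-B:5"),
                                         pair_info_row("A:6-B:7")))
  map <- build_interaction_map(cs)
  expect_identical(map$pair, c("A:6-B:7", "A:2-B:3"))
  expect_identical(map$persistence, c(0.19, 0.10))
  expect_equal(count_intermolecular(map), 2)
})

test_that("raising the threshold never adds entries", {
  set.seed(17)
  inc <- matrix(runif(50 * 8) < rep(runif(8, 0, 0.6), each = 50), 50, 8)
  colnames(inc) <- sprintf("A:%d-B:%d", 1:8, 8:1)
  info <- do.call(rbind, lapply(colnames(inc), pair_info_row))
  cs <- series_from_incidence(inc, info)
  sizes <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8),
                  function(th) nrow(build_interaction_map(cs, threshold = th)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("near-diagonal intramolecular pairs are excluded, others kept", {
  inc <- matrix(TRUE, 10, 3,
                dimnames = list(NULL, c("A:3-A:5", "A:3-A:6", "A:2-B:3")))
  info <- rbind(pair_info_row("A:3-A:5", "intramolecular"),
                pair_info_row("A:3-A:6", "intramolecular"),
                pair_info_row("A:2-B:3", "intermolecular"))
  cs <- series_from_incidence(inc, info)
  map <- build_interaction_map(cs)                 # default window |i-j| <= 2
  expect_setequal(map$pair, c("A:3-A:6", "A:2-B:3"))
  expect_equal(count_intermolecular(map), 1)
  map3 <- build_interaction_map(cs, exclusion = 3L)
  expect_identical(map3$pair, "A:2-B:3")
  # an all-zero series yields an empty map
  inc0 <- matrix(FALSE, 10, 1, dimnames = list(NULL, "A:1-B:1"))
  cs0 <- series_from_incidence(inc0, pair_info_row("A:1-B:1"))
  expect_equal(nrow(build_interaction_map(cs0)), 0)
  expect_equal(count_intermolecular(build_interaction_map(cs0)), 0)
})

test_that("map entries are typed from the topology and sorted by persistence", {
  spec <- builtin_peptides()$P1M2
  inc <- matrix(FALSE, 100, 2,
                dimnames = list(NULL, c("A:3-B:8", "A:2-B:9")))
  inc[1:98, 1] <- TRUE
  inc[1:50, 2] <- TRUE
  cs <- series_from_incidence(inc, rbind(pair_info_row("A:3-B:8"),
                                         pair_info_row("A:2-B:9")),
                              topology = list(A = spec, B = spec))
  map <- build_interaction_map(cs)
  expect_identical(map$pair, c("A:3-B:8", "A:2-B:9"))
  expect_identical(map$category, c("R_pT_saltbridge", "other_contact"))
  expect_true(map$donor_modified[1])
})

test_that("interaction maps export TSV and diagram-ready JSON", {
  inc <- matrix(FALSE, 100, 2,
                dimnames = list(NULL, c("A:3-B:8", "A:2-B:9")))
  inc[1:98, 1] <- TRUE
  inc[1:10, 2] <- TRUE
  cs <- series_from_incidence(inc, rbind(pair_info_row("A:3-B:8"),
                                         pair_info_row("A:2-B:9")))
  map <- build_interaction_map(cs)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  doc <- write_interaction_map(map, tsv, js)
  back <- read.delim(tsv)
  expect_equal(back$persistence, c(0.98, 0.10))
  parsed <- jsonlite::read_json(js)
  widths <- vapply(parsed$entries, function(e) e$line_width, numeric(1))
  # line widths grow linearly from thinnest at the threshold to thickest at 98%
  expect_equal(widths[1], 5.0, tolerance = 1e-6)
  expect_equal(widths[2], 0.5, tolerance = 1e-6)
})
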