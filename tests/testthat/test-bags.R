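## a small selection over a crafted dataset used throughout
make_selection <- function(data, selected) {
  coefs <- setNames(rep(1, length(selected)), selected)
  structure(list(selected = selected, coefficients = coefs, intercept = 0,
                 lambda = 0.1,
                 weights = setNames(rep(1, length(data$var_ids)),
                                    data$var_ids),
                 method = "lasso"), class = "bag_selection")
}

test_that("zero-size correlation bags are empty and the shortlist is S", {
  d <- random_dataset(30, 6, seed = 1)
  sel <- make_selection(d, c("x1", "x4"))
  bags <- bag_correlation_topq(sel, d, q = 0)
  expect_equal(nrow(bags$members), 0)
  expect_equal(shortlist_union(bags), c("x1", "x4"))
})

test_that("an exact duplicate of the owner ranks first with correlation 1", {
  set.seed(2)
  X <- matrix(rnorm(80), 20, 4)
  X <- cbind(X, X[, 1])
  d <- bag_dataset(X, rnorm(20), var_ids = c("a", "b", "c", "e", "adup"))
  sel <- make_selection(d, "a")
  bags <- bag_correlation_topq(sel, d, q = 2)
  top <- bags$members[bags$members$rank == 1, ]
  expect_equal(top$candidate, "adup")
  expect_equal(top$score, 1, tolerance = 1e-12)
})

test_that("correlation bags match an exhaustive sort of the correlation row", {
  d <- random_dataset(25, 6, seed = 3)
  sel <- make_selection(d, c("x2", "x5"))
  C <- cor(d$X)
  for (ranking in c("signed", "absolute")) {
    bags <- bag_correlation_topq(sel, d, q = 3, ranking = ranking)
    for (j in sel$selected) {
      r <- C[j, ]; r <- r[names(r) != j]
      key <- if (ranking == "signed") r else abs(r)
      want <- names(sort(key, decreasing = TRUE))[1:3]
      got <- bags$members$candidate[bags$members$owner == j]
      expect_equal(got, want)
    }
  }
  ## oversized q is capped with a warning
  expect_warning(bigq <- bag_correlation_topq(sel, d, q = 10), "capping")
  expect_equal(sum(bigq$members$owner == "x2"), 5)
})

test_that("threshold bags equal a brute-force filter and respect the cutoff", {
  d <- random_dataset(25, 6, seed = 4)
  sel <- make_selection(d, c("x1", "x3"))
  C <- cor(d$X)
  bags <- bag_correlation_threshold(sel, d, threshold = 0.2)
  for (j in sel$selected) {
    r <- C[j, ]; r <- r[names(r) != j]
    want <- sort(names(r)[r >= 0.2])
    got <- sort(bags$members$candidate[bags$members$owner == j])
    expect_equal(got, want)
  }
  expect_true(all(bags$members$score >= 0.2))
  expect_error(bag_correlation_threshold(sel, d, threshold = 0), "threshold")
  ## threshold 1: only exact duplicates qualify
  X <- matrix(rnorm(60), 20, 3)
  X <- cbind(X, X[, 2])
  dd <- bag_dataset(X, rnorm(20), var_ids = c("a", "b", "c", "bdup"))
  sel2 <- make_selection(dd, "b")
  b1 <- bag_correlation_threshold(sel2, dd, threshold = 1)
  expect_equal(b1$members$candidate, "bdup")
})

test_that("raising the threshold never adds a bag member", {
  d <- random_dataset(40, 10, seed = 5)
  sel <- make_selection(d, c("x1", "x6", "x9"))
  prev <- NULL
  for (thr in c(0.05, 0.15, 0.3, 0.6)) {
    cur <- bag_correlation_threshold(sel, d, threshold = thr)$members
    if (!is.null(prev)) {
      expect_true(all(paste(cur$owner, cur$candidate) %in%
                        paste(prev$owner, prev$candidate)))
    }
    prev <- cur
  }
})

test_that("replacement-MSE bags match an exhaustive OLS oracle", {
  d <- random_dataset(30, 8, seed = 6, beta = c(1, -1, 0.5, rep(0, 5)),
                      sigma = 0.5)
  sel <- make_selection(d, c("x1", "x2", "x3"))
  bags <- bag_mse_topq(sel, d, q = 3)
  n <- nrow(d$X)
  for (j in sel$selected) {
    pool <- setdiff(d$var_ids, sel$selected)
    mses <- vapply(pool, function(k) {
      vars <- c(setdiff(sel$selected, j), k)
      f <- refit_ols(vars, d)
      mean((d$y - predict(f, d))^2)
    }, numeric(1))
    want <- names(sort(mses))[1:3]
    got <- bags$members$candidate[bags$members$owner == j]
    expect_equal(got, want)
    expect_equal(bags$members$score[bags$members$owner == j],
                 unname(sort(mses)[1:3]), tolerance = 1e-10)
  }
})

test_that("B3 excludes selected variables from the candidate pool", {
  d <- random_dataset(30, 8, seed = 7)
  sel <- make_selection(d, c("x1", "x2"))
  bags <- bag_mse_topq(sel, d, q = 6)
  expect_false(any(bags$members$candidate %in% sel$selected))
})

test_that("in a noiseless design the generating covariate beats pure noise", {
  set.seed(8)
  X <- matrix(rnorm(200), 50, 4)
  colnames(X) <- c("sig", "noise1", "noise2", "decoy")
  y <- X[, "sig"] * 2
  d <- bag_dataset(cbind(X, stand_in = rnorm(50)), y)
  sel <- make_selection(d, "decoy")
  bags <- bag_mse_topq(sel, d, q = 4)
  expect_equal(bags$members$candidate[bags$members$rank == 1], "sig")
})

test_that("MSE ratios are brute-force ratios with 1 for self and duplicates", {
  set.seed(9)
  X <- matrix(rnorm(120), 30, 4)
  X <- cbind(X, X[, 1])
  d <- bag_dataset(X, X[, 1] + rnorm(30, sd = 0.5),
                   var_ids = c("a", "b", "c", "e", "adup"))
  sel <- make_selection(d, c("a", "b"))
  expect_equal(mse_ratio("a", "a", sel, d), 1, tolerance = 1e-12)
  expect_equal(mse_ratio("adup", "a", sel, d), 1, tolerance = 1e-10)
  f_ab <- refit_ols(c("a", "b"), d)
  f_cb <- refit_ols(c("c", "b"), d)
  want <- mean((d$y - predict(f_cb, d))^2) / mean((d$y - predict(f_ab, d))^2)
  expect_equal(mse_ratio("c", "a", sel, d), want, tolerance = 1e-10)
})

test_that("B3 scores are invariant to the column order of the design", {
  d <- random_dataset(30, 6, seed = 10, beta = c(1, 1, rep(0, 4)))
  sel <- make_selection(d, c("x1", "x2"))
  bags <- bag_mse_topq(sel, d, q = 4)
  perm <- c(4, 2, 6, 1, 3, 5)
  d2 <- bag_dataset(d$X[, perm], d$y, var_ids = d$var_ids[perm],
                    standardize = FALSE)
  sel2 <- make_selection(d2, c("x1", "x2"))
  bags2 <- bag_mse_topq(sel2, d2, q = 4)
  m1 <- bags$members[order(bags$members$owner, bags$members$candidate), ]
  m2 <- bags2$members[order(bags2$members$owner, bags2$members$candidate), ]
  expect_equal(m1$candidate, m2$candidate)
  expect_equal(m1$score, m2$score, tolerance = 1e-10)
})

test_that("bags depend only on the stage-1 portion", {
  d <- random_dataset(90, 8, seed = 11, beta = c(1, rep(0, 7)))
  sp <- split_three_way(d, seed = 1)
  sel <- make_selection(sp$d1, c("x1", "x5"))
  before <- list(bag_correlation_topq(sel, sp$d1, q = 3),
                 bag_mse_topq(sel, sp$d1, q = 3))
  sp$d2$X[] <- 0; sp$d3$y[] <- 99   # perturb the other portions
  after <- list(bag_correlation_topq(sel, sp$d1, q = 3),
                bag_mse_topq(sel, sp$d1, q = 3))
  expect_identical(before, after)
})

test_that("the shortlist is a deduplicated union, owners first", {
  d <- random_dataset(30, 8, seed = 12)
  sel <- make_selection(d, c("x1", "x2", "x3"))
  bags <- bag_correlation_topq(sel, d, q = 4)
  short <- shortlist_union(bags)
  expect_equal(anyDuplicated(short), 0)
  expect_equal(short[1:3], sel$selected)
  expect_setequal(short, unique(c(sel$selected, bags$members$candidate)))
  expect_lte(length(short), length(sel$selected) * (4 + 1))
})

test_that("the elicitation worksheet round-trips and rejects blanks", {
  d <- random_dataset(30, 6, seed = 13)
  sel <- make_selection(d, c("x1", "x4"))
  bags <- bag_correlation_topq(sel, d, q = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_worksheet(bags, f)
  ws <- readr::read_csv(f, show_col_types = FALSE)
  expect_true(all(is.na(ws$relevant)))
  expect_error(read_worksheet(f), "x1")      # untouched sheet: incomplete
  ws$relevant <- as.integer(ws$candidate %in% c("x1", "x2"))
  readr::write_csv(ws, f)
  rel <- read_worksheet(f)
  expect_true(rel[["x1"]])
  expect_false(rel[["x4"]])
  expect_setequal(names(rel), shortlist_union(bags))
  ## inconsistent duplicate labels are refused
  ws$relevant[ws$candidate == ws$candidate[1]][1] <- 1L - ws$relevant[
    ws$candidate == ws$candidate[1]][1]
  if (sum(ws$candidate == ws$candidate[1]) > 1) {
    readr::write_csv(ws, f)
    expect_error(read_worksheet(f), "inconsistent")
  }
})
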