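ann2 <- function(ids, ot) data.frame(feature_id = ids, odor_threshold = ot)

test_that("ROAV follows the OAV ratio formula", {
  res <- computeROAV(c(A = 5, B = 1), ann2(c("A", "B"), c(1, 1)))
  expect_equal(res$oav, c(5, 1))
  expect_equal(res$roav, c(100, 20))
  expect_identical(res$contribution_class, c("key", "key"))
})

test_that("ROAV is invariant to global rescaling of contents", {
  set.seed(71)
  contents <- setNames(rlnorm(30), paste0("V", 1:30))
  ann <- ann2(names(contents), 10^runif(30, -3, 0))
  r1 <- computeROAV(contents, ann)
  for (k in c(0.001, 3, 1e6)) {
    r2 <- computeROAV(contents * k, ann)
    expect_equal(r2$roav, r1$roav, tolerance = 1e-12)
  }
})

test_that("ROAV matches an independent two-pass oracle", {
  set.seed(72)
  contents <- setNames(rlnorm(30), paste0("V", 1:30))
  ot <- 10^runif(30, -3, 0)
  res <- computeROAV(contents, ann2(names(contents), ot))
  # oracle: explicit max pass then ratio pass
  oav <- numeric(30)
  for (i in 1:30) oav[i] <- contents[i] / ot[i]
  mx <- -Inf
  for (i in 1:30) if (oav[i] > mx) mx <- oav[i]
  expect_equal(res$oav, oav, tolerance = 1e-12)
  expect_equal(res$roav, 100 * oav / mx, tolerance = 1e-12)
  # rank preservation and a unique maximum at 100
  expect_identical(order(res$roav), order(res$oav))
  expect_equal(max(res$roav), 100)
  expect_equal(sum(res$roav == 100), 1L)
})

test_that("compounds without thresholds are unscored and never the reference", {
  contents <- c(A = 1000, B = 1)
  res <- computeROAV(contents, data.frame(feature_id = c("A", "B"),
                                          odor_threshold = c(NA, 0.5)))
  expect_true(is.na(res$roav[res$feature_id == "A"]))
  expect_equal(res$roav[res$feature_id == "B"], 100)
  expect_error(computeROAV(c(A = 1), ann2("A", NA)), "odor threshold")
  expect_error(computeROAV(c(A = 0), ann2("A", 1)), "zero")
})

test_that("contribution class boundaries are literal", {
  expect_identical(classifyContribution(c(1.0001, 1.0, 0.1, 0.0999, 100)),
                   c("key", "moderate", "moderate", "minor", "key"))
})

test_that("tied maxima all score 100", {
  res <- computeROAV(c(A = 2, B = 2, C = 1), ann2(c("A", "B", "C"), c(1, 1, 1)))
  expect_equal(res$roav[1:2], c(100, 100))
})

test_that("class composition sums to 100 per group and matches hand sums", {
  s <- smallStudy(seed = 73)
  prep <- preprocessTable(s$vocs)$table
  comp <- classComposition(prep, s$annotations)
  expect_equal(unname(colSums(comp)), rep(100, 3), tolerance = 1e-9)
  # hand-summed oracle for one group and one class
  means <- groupMeanContents(prep)[, "GL"]
  cls <- s$annotations$chemical_class[match(names(means),
                                            s$annotations$feature_id)]
  expect_equal(comp["alcohols", "GL"],
               100 * sum(means[cls == "alcohols"]) / sum(means))
  # single-class table gives 100%
  one <- classComposition(prep[1:3, ],
                          transform(s$annotations,
                                    chemical_class = "ketones"))
  expect_equal(unname(one["ketones", ]), rep(100, 3))
  # two classes with equal total content split 50/50
  m <- matrix(c(2, 2), 1, 2, dimnames = list("s1", c("a", "b")))
  tab <- featureTable(m, "G")
  cc <- classComposition(tab, data.frame(feature_id = c("a", "b"),
                                         chemical_class = c("esters",
                                                            "ketones")))
  expect_equal(unname(cc[, 1]), c(50, 50))
  # unannotated features fall into "others" with a warning
  expect_warning(classComposition(tab, data.frame(feature_id = "a",
                                                  chemical_class = "esters")),
                 "others")
})

test_that("venn partition covers the closed-form cases", {
  same <- vennPartition(list(A = letters[1:5], B = letters[1:5],
                             C = letters[1:5]))
  expect_equal(unname(same["A:B:C"]), 5L)
  expect_equal(sum(same), 5L)
  disj <- vennPartition(list(A = letters[1:2], B = letters[3:5],
                             C = letters[6]))
  expect_equal(unname(disj[c("A", "B", "C")]), c(2L, 3L, 1L))
  expect_equal(sum(disj[4:7]), 0L)
})

test_that("venn regions partition the union on random set triples", {
  set.seed(74)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(letters, sample(0:20, 1)))
    names(sets) <- c("A", "B", "C")
    v <- vennPartition(sets)
    expect_equal(sum(v), length(unique(unlist(sets))))
    expect_equal(unname(v), vennOracle(sets$A, sets$B, sets$C))
    # per-group totals are recoverable from the regions
    expect_equal(unname(v["A"] + v["A:B"] + v["A:C"] + v["A:B:C"]),
                 length(unique(sets$A)))
  }
})

test_that("sensory networks keep the top attributes by degree", {
  ann <- data.frame(feature_id = c("V1", "V2", "V3"),
                    descriptors = c("sweet;fruity", "sweet", "sweet;green"))
  net <- buildSensoryNetwork(c("V1", "V2", "V3"), ann, top_k = 1)
  expect_identical(net$attributes$attribute, "sweet")
  expect_equal(net$attributes$degree, 3L)
  expect_equal(nrow(net$edges), 3L)
  # single VOC, two descriptors
  one <- buildSensoryNetwork("V1", ann, top_k = 10)
  expect_equal(nrow(one$edges), 2L)
  expect_true(all(one$attributes$degree == 1L))
  # ties broken lexicographically
  tie <- buildSensoryNetwork(c("V1", "V3"), ann, top_k = 2)
  expect_identical(tie$attributes$attribute, c("sweet", "fruity"))
  # the graph is bipartite: edges only between VOC and attribute nodes
  expect_true(igraph::is_bipartite(net$graph))
})

test_that("attribute retention is invariant to VOC input order", {
  set.seed(75)
  ids <- paste0("V", 1:20)
  ann <- data.frame(feature_id = ids,
                    descriptors = replicate(20, paste(
                      sample(c("sweet", "fruity", "green", "waxy",
                               "ethereal", "floral"), sample(1:4, 1)),
                      collapse = ";")))
  a <- buildSensoryNetwork(ids, ann, top_k = 3)
  b <- buildSensoryNetwork(rev(ids), ann, top_k = 3)
  expect_identical(a$attributes, b$attributes)
  # degree ranking matches a brute-force count
  counts <- sort(table(unlist(strsplit(ann$descriptors, ";"))),
                 decreasing = TRUE)
  expect_setequal(a$attributes$degree,
                  as.integer(counts[a$attributes$attribute]))
  expect_warning(buildSensoryNetwork(
    "V1", data.frame(feature_id = "V1", descriptors = ""), top_k = 2),
    "empty network")
})
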