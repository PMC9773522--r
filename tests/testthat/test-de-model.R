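test_that("design matrices use treatment coding with a sex contrast", {
  md <- data.frame(sex = c("male", "male", "female", "female"))
  X <- buildDesign(md, covariates = "sex")
  expect_equal(dim(X), c(4L, 2L))
  expect_equal(qr(X)$rank, 2)
  expect_equal(attr(X, "contrast"), "sexfemale")
  # male is the reference: female indicator is 0/0/1/1
  expect_equal(unname(X[, "sexfemale"]), c(0, 0, 1, 1))

  # batch perfectly confounded with sex is rejected, naming the column
  md2 <- data.frame(sex = c("male", "male", "female", "female"),
                    batch = c("b1", "b1", "b2", "b2"))
  expect_error(buildDesign(md2, covariates = c("sex", "batch")),
               "rank deficient.*batch")
  expect_error(buildDesign(md, covariates = c("sex", "nope")), "missing")
  expect_error(buildDesign(data.frame(sex = c("male", NA, "female")),
                           covariates = "sex"), "missing values")
})

test_that("design column count follows treatment coding on simulated metadata", {
  d <- simulationDesign(nFemale = 10, nMale = 10, nGenesAutosomalNull = 10,
                        nBatches = 2, replicateCountPerSample = 1, seed = 41)
  cs <- simulateExperiment(d)$countSet
  md <- as.data.frame(SummarizedExperiment::colData(cs))
  X <- buildDesign(md, covariates = c("sex", "batch", "lane",
                                      "birth_weight_kg", "ancestry_pc1",
                                      "ancestry_pc2"))
  nb <- length(unique(md$batch)); nl <- length(unique(md$lane))
  expect_equal(ncol(X), 1 + 1 + (nb - 1) + (nl - 1) + 3)
  expect_equal(qr(X)$rank, ncol(X))
})

test_that("per-gene weighted least squares matches direct solutions", {
  set.seed(5)
  m <- 8
  design <- cbind(intercept = 1, sexfemale = rep(c(0, 1), each = 4))
  attr(design, "contrast") <- "sexfemale"
  E <- matrix(rnorm(5 * m, 5), 5, m,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:m)))

  # unit weights reduce to ordinary least squares
  fit <- fitGeneModels(E, weights = matrix(1, 5, m), design = design)
  fit0 <- fitGeneModels(E, weights = NULL, design = design)
  for (g in 1:5) {
    ls <- lm(E[g, ] ~ design[, 2])
    expect_equal(fit$coef[g], unname(coef(ls)[2]), tolerance = 1e-10)
    expect_equal(fit0$coef[g], unname(coef(ls)[2]), tolerance = 1e-10)
    expect_equal(fit$s2[g], sum(residuals(ls)^2) / (m - 2), tolerance = 1e-10)
  }
  expect_equal(fit$df, m - 2)

  # arbitrary positive weights match the weighted normal equations
  W <- matrix(runif(5 * m, 0.2, 3), 5, m)
  fitW <- fitGeneModels(E, weights = W, design = design)
  for (g in 1:5) {
    A <- t(design) %*% diag(W[g, ]) %*% design
    b <- t(design) %*% diag(W[g, ]) %*% E[g, ]
    beta <- solve(A, b)
    expect_equal(fitW$coef[g], beta[2], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(fitW$stdevUnscaled[g], sqrt(solve(A)[2, 2]),
                 tolerance = 1e-10)
  }

  # an exactly linear response leaves zero residual variance
  E2 <- E
  E2[1, ] <- 2 + 3 * design[, 2]
  fit2 <- fitGeneModels(E2, weights = NULL, design = design)
  expect_lt(fit2$s2[1], 1e-20)
  expect_error(fitGeneModels(E * NA, weights = NULL, design = design),
               "non-finite")
})

test_that("moderation limits recover the classical and pooled statistics", {
  set.seed(6)
  m <- 10
  design <- cbind(intercept = 1, sexfemale = rep(c(0, 1), each = 5))
  attr(design, "contrast") <- "sexfemale"
  E <- matrix(rnorm(30 * m, 5), 30, m,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:m)))
  fit <- fitGeneModels(E, weights = NULL, design = design)

  # d0 = 0: moderated t equals the ordinary per-gene t
  m0 <- ebayesModerate(fit, priorDf = 0)
  tOrd <- fit$coef / (fit$stdevUnscaled * sqrt(fit$s2))
  expect_equal(m0@t, tOrd, tolerance = 1e-10)
  expect_equal(m0@p, 2 * pt(-abs(tOrd), df = fit$df), tolerance = 1e-10)

  # d0 = Inf with a given prior variance: pooled z-style statistic
  mInf <- ebayesModerate(fit, priorDf = Inf, priorVar = 0.8)
  expect_equal(mInf@t, fit$coef / (fit$stdevUnscaled * sqrt(0.8)),
               tolerance = 1e-10)
  expect_equal(mInf@p, 2 * pnorm(-abs(mInf@t)), tolerance = 1e-10)

  # identical residual variances: estimated d0 = Inf, posterior = that value
  fitC <- fit
  fitC$s2 <- rep(0.5, 30)
  mC <- ebayesModerate(fitC)
  expect_equal(mC@d0, Inf)
  expect_equal(unique(round(mC@s2post, 12)), 0.5)

  # posterior variance lies between prior and residual variances
  mE <- ebayesModerate(fit)
  expect_true(all(mE@s2post >= pmin(mE@s0sq, mE@s2) - 1e-12))
  expect_true(all(mE@s2post <= pmax(mE@s0sq, mE@s2) + 1e-12))
  expect_error(ebayesModerate(structure(list(genes = "g", coef = 1,
                                             stdevUnscaled = 1, s2 = 0,
                                             df = 5, avgLogCPM = 1,
                                             coefName = "x"),
                                        class = "geneFit"), priorDf = 0),
               "zero")
})

test_that("moment matching recovers a planted scaled-F variance prior", {
  set.seed(8)
  d0 <- 4; s0sq <- 0.25; d <- 10; n <- 5000
  s2 <- s0sq * rf(n, d, d0)
  fit <- structure(list(genes = paste0("g", 1:n), coef = rnorm(n),
                        stdevUnscaled = rep(0.5, n), s2 = s2, df = d,
                        avgLogCPM = rnorm(n, 5), coefName = "sexfemale"),
                   class = "geneFit")
  mfit <- ebayesModerate(fit)
  expect_gt(mfit@d0, 2.8)
  expect_lt(mfit@d0, 5.6)
  expect_lt(abs(mfit@s0sq - s0sq) / s0sq, 0.15)
  # independent cross-check against the reference moment-matching fit
  ref <- limma::fitFDist(s2, df1 = d)
  expect_equal(mfit@d0, ref$df2, tolerance = 1e-6)
  expect_equal(mfit@s0sq, ref$scale, tolerance = 1e-6)
})

test_that("BH adjustment equals the step-up oracle and p.adjust", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(10)
  for (i in 1:5) {
    p <- runif(sample(5:50, 1))
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
    expect_equal(bhAdjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(bhAdjust(p) >= p))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("result tables order, label and subset correctly", {
  d <- simulationDesign(nFemale = 10, nMale = 10, nGenesAutosomalNull = 300,
                        nGenesAutosomalSexDE = 30, nGenesXEscape = 10,
                        nGenesYLinked = 5, replicateCountPerSample = 1,
                        seed = 55)
  sim <- simulateExperiment(d)
  res <- runDEAnalysis(sim$countSet, covariates = "sex")
  tab <- res$table
  expect_true(!is.unsorted(tab$adj.P.Val))
  expect_true(all(tab$adj.P.Val >= tab$P.Value - 1e-15))
  expect_true(all(tab$direction %in% c("female_up", "male_up")))

  # planted female-up X escapers are recovered with the right direction
  xesc <- intersect(tab$gene, sim$truth$gene[sim$truth$gene_class == "X" &
                                             sim$truth$is_sexde &
                                             sim$truth$true_log2fc_f_vs_m > 0])
  sig <- tab[tab$gene %in% xesc & tab$significant, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$direction == "female_up"))

  # subsetting re-runs BH over the subset only
  sub <- head(tab$gene, 10)
  tabSub <- deTable(res$fit, alpha = 0.05, subset = sub)
  expect_setequal(tabSub$gene, sub)
  expect_equal(sort(tabSub$adj.P.Val),
               sort(bhAdjust(tab$P.Value[match(tabSub$gene, tab$gene)])))
  expect_error(deTable(res$fit, subset = "NOT_A_GENE"), "subset")

  counts <- summarizeDEByClass(tab)
  expect_true(all(counts$n > 0))
})

test_that("modeling a planted batch effect restores type-I control", {
  set.seed(77)
  m <- 40
  sex <- rep(c("female", "male"), each = m / 2)
  # batch is deliberately correlated with sex (16/4 vs 4/16)
  batch <- c(rep("b1", 16), rep("b2", 4), rep("b1", 4), rep("b2", 16))
  n <- 500
  delta <- rnorm(n, 0, 1)
  E <- matrix(rnorm(n * m, 5, 0.5), n, m,
              dimnames = list(paste0("g", 1:n), paste0("s", 1:m)))
  E <- E + outer(delta, as.numeric(batch == "b2"))
  md <- data.frame(sex = sex, batch = batch)

  fpRate <- function(covs) {
    X <- buildDesign(md, covariates = covs)
    fit <- fitGeneModels(E, weights = NULL, design = X)
    mean(ebayesModerate(fit)@p < 0.05)
  }
  fpWith <- fpRate(c("sex", "batch"))
  fpWithout <- fpRate("sex")
  expect_gt(fpWithout, 0.25)   # badly inflated without the covariate
  expect_lt(fpWith, 0.08)      # controlled with it
  expect_lt(fpWith, fpWithout)
})
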