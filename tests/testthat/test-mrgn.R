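panel <- function(u = "S", c3 = "S", cb = "S", f = "S") {
  c(ureidopenicillins = u, cephalosporins = c3, carbapenems = cb,
    fluoroquinolones = f)
}
ECOLI <- "112283007"
PA <- "52499004"

test_that("each classification sentence is reproduced", {
  # carbapenemase forces 4MRGN irrespective of susceptibility results
  expect_identical(mrgn_classify(ECOLI, panel(), carbapenemase = TRUE)$category,
                   "4MRGN")
  # carbapenem resistance forces 4MRGN outside P. aeruginosa
  expect_identical(mrgn_classify(ECOLI, panel(cb = "R"))$category, "4MRGN")
  # ... but not for P. aeruginosa, where one resistant group is below threshold
  pa <- mrgn_classify(PA, panel(cb = "R"))
  expect_identical(pa$category, "none")
  expect_identical(pa$n_resistant, 1L)
  # the exception is inherited by the P. aeruginosa subtree
  expect_identical(mrgn_classify("990001001", panel(cb = "R"))$category,
                   "none")
  # three of four resistant
  expect_identical(mrgn_classify(ECOLI, panel("R", "R", "S", "R"))$category,
                   "3MRGN")
  # two of four resistant is 2MRGN only in neonatology
  expect_identical(mrgn_classify(ECOLI, panel("R", "R"),
                                 neonatology = TRUE)$category, "2MRGN")
  none <- mrgn_classify(ECOLI, panel("R", "R"))
  expect_identical(none$category, "none")
  expect_identical(none$rationale, "two-group-non-neonatology")
})

test_that("the classifier matches the brute-force oracle on the full grid", {
  grid <- mrgn_grid()
  expect_identical(nrow(grid), 2048L)
  got <- character(nrow(grid))
  want <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- c(ureidopenicillins = grid$ureidopenicillins[i],
           cephalosporins = grid$cephalosporins[i],
           carbapenems = grid$carbapenems[i],
           fluoroquinolones = grid$fluoroquinolones[i])
    got[i] <- mrgn_classify(if (grid$pa[i]) PA else ECOLI, g,
                            carbapenemase = grid$carbapenemase[i],
                            neonatology = grid$neonatology[i])$category
    want[i] <- mrgn_oracle(grid$pa[i], g, grid$carbapenemase[i],
                           grid$neonatology[i])
  }
  expect_identical(got, want)
  # frozen category totals over the full grid (regression fixture)
  expect_identical(as.integer(table(factor(got,
    levels = c("2MRGN", "3MRGN", "4MRGN", "none")))),
    c(81L, 30L, 1154L, 783L))
})

test_that("moving any group from S to R never lowers the category", {
  rank <- c(none = 0, `2MRGN` = 2, `3MRGN` = 3, `4MRGN` = 4)
  grid <- mrgn_grid()
  grid <- grid[grid$ureidopenicillins != "R", , drop = FALSE]
  idx <- sample(seq_len(nrow(grid)), 200)   # spot-check the escalation
  for (i in idx) {
    g <- c(ureidopenicillins = grid$ureidopenicillins[i],
           cephalosporins = grid$cephalosporins[i],
           carbapenems = grid$carbapenems[i],
           fluoroquinolones = grid$fluoroquinolones[i])
    before <- mrgn_classify(if (grid$pa[i]) PA else ECOLI, g,
                            carbapenemase = grid$carbapenemase[i],
                            neonatology = grid$neonatology[i])$category
    g[["ureidopenicillins"]] <- "R"
    after <- mrgn_classify(if (grid$pa[i]) PA else ECOLI, g,
                           carbapenemase = grid$carbapenemase[i],
                           neonatology = grid$neonatology[i])$category
    expect_gte(rank[[after]], rank[[before]])
  }
})

test_that("carbapenemase detection dominates every other field", {
  grid <- mrgn_grid()
  grid <- grid[grid$carbapenemase, , drop = FALSE]
  for (i in sample(seq_len(nrow(grid)), 50)) {
    g <- c(ureidopenicillins = grid$ureidopenicillins[i],
           cephalosporins = grid$cephalosporins[i],
           carbapenems = grid$carbapenems[i],
           fluoroquinolones = grid$fluoroquinolones[i])
    res <- mrgn_classify(if (grid$pa[i]) PA else ECOLI, g,
                         carbapenemase = TRUE,
                         neonatology = grid$neonatology[i])
    expect_identical(res$category, "4MRGN")
    expect_identical(res$rationale[1], "carbapenemase-4mrgn")
  }
})

test_that("counting I as resistant is available but off by default", {
  g <- panel("I", "I", "S", "I")
  expect_identical(mrgn_classify(ECOLI, g)$category, "none")
  expect_identical(mrgn_classify(ECOLI, g,
                                 count_intermediate = TRUE)$category, "3MRGN")
})

test_that("input problems raise and marginal inputs warn", {
  expect_error(mrgn_classify(ECOLI, c(ureidopenicillins = "R")), "missing")
  expect_error(mrgn_classify(ECOLI, panel("X")), "S, I, R or NT")
  nt <- mrgn_classify(ECOLI, panel("R", "R", "NT", "R"))
  expect_identical(nt$category, "3MRGN")
  expect_match(nt$warnings, "not tested", all = FALSE)
  gp <- mrgn_classify("3092008", panel(cb = "R"))   # S. aureus, Gram-positive
  expect_identical(gp$category, "4MRGN")            # still computed
  expect_match(gp$warnings, "Gram-negative", all = FALSE)
})

test_that("results encode as observations with the matching answer code", {
  three <- mrgn_classify(ECOLI, panel("R", "R", "S", "R"))
  obs <- mrgn_to_observation(three, id = "mrgn-1")
  expect_identical(obs$value$code, "LA33215-7")
  four <- mrgn_classify(ECOLI, panel(cb = "R"))
  expect_identical(mrgn_to_observation(four, id = "mrgn-2")$value$code,
                   "LA33216-5")
  expect_identical(nrow(validate_resource(to_fhir(obs))), 0L)
  none <- mrgn_classify(ECOLI, panel())
  expect_error(mrgn_to_observation(none, id = "mrgn-3"), "cannot be encoded")
})

test_that("the table interface classifies row-wise", {
  df <- data.frame(
    isolate_id = c("i1", "i2"), species_code = c(ECOLI, PA),
    ureidopenicillins = c("S", "S"), cephalosporins = c("S", "S"),
    carbapenems = c("S", "R"), fluoroquinolones = c("S", "S"),
    carbapenemase = c("true", "false"), neonatology = c("false", "false"),
    stringsAsFactors = FALSE)
  out <- classify_mrgn_table(df)
  expect_identical(out$category, c("4MRGN", "none"))
  expect_identical(out$answer_code, c("LA33216-5", NA_character_))
  expect_error(classify_mrgn_table(df[, -3]), "missing column")
})
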