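test_that("a single instance is selected with no supplementary ROIs", {
  s <- small_sim(seed = 2, nSubjects = 3L, nRois = 6L, nTime = 20L,
                 instanceSizes = c(6L), frontalCounts = 4L)
  sel <- selectMain(s$stack, s$sim$instances)
  expect_identical(mainInstance(sel), "atlasA")
  expect_length(suppRois(sel), 0L)
  fus <- fuseNetworks(s$stack, sel)
  expect_identical(fusedRois(fus), mainRois(sel))
  expect_identical(fusedIndex(fus), 0L)
  expect_length(pvalueTrace(fus), 1L)
})

test_that("instance ROIs absent from the stack are rejected", {
  s <- small_sim(seed = 2, nSubjects = 3L, nRois = 8L, nTime = 20L,
                 instanceSizes = c(4L, 4L))
  stranger <- toy_instance(3L, atlas = "elsewhere")
  expect_error(selectMain(s$stack, c(s$sim$instances, list(stranger))),
               "absent from the stack")
})

test_that("exact instance-level ties resolve to first input order", {
  s <- small_sim(seed = 6, nSubjects = 3L, nRois = 8L, nTime = 20L,
                 instanceSizes = c(4L, 4L))
  # duplicate the first instance's signal structure under a new atlas name:
  # the two candidates then have identical index matrices and p-values
  stack <- s$stack
  inst1 <- s$sim$instances[[1]]
  tab <- roiTable(inst1); tab$atlas <- "atlasZ"
  ghost <- NetworkInstance("synFPN", "atlasZ", tab)
  stackTab <- roiTable(stack)
  dup <- stackTab[match(roiKeys(inst1), paste(stackTab$atlas, stackTab$roi_id,
                                              sep = ":")), ]
  dup$atlas <- "atlasZ"
  bigTab <- rbind(stackTab, dup)
  n0 <- nrow(stackTab); n1 <- nrow(bigTab)
  idx <- c(seq_len(n0), match(roiKeys(inst1),
                              paste(stackTab$atlas, stackTab$roi_id, sep = ":")))
  mats <- array(NA_real_, c(2, 3, n1, n1))
  pvs <- mats
  for (ci in 1:2) for (si in 1:3) {
    mats[ci, si, , ] <- stack@matrices[ci, si, idx, idx]
    pvs[ci, si, , ] <- stack@pvals[ci, si, idx, idx]
  }
  stack2 <- new("ConditionStack", conditions = conditions(stack),
                subjects = subjects(stack), rois = bigTab,
                matrices = mats, pvals = pvs)
  sel <- selectMain(stack2, list(s$sim$instances[[1]], ghost))
  expect_identical(mainInstance(sel), "atlasA")
  ps <- instancePvalues(sel)
  expect_equal(unname(ps["atlasA"]), unname(ps["atlasZ"]))
})

test_that("fusion equals exhaustive prefix evaluation on small stacks", {
  for (seed in c(101, 202, 303)) {
    s <- small_sim(seed = seed, nSubjects = 4L, nRois = 12L, nTime = 40L,
                   instanceSizes = c(3L, 4L, 3L, 2L))
    sel <- selectMain(s$stack, s$sim$instances)
    fus <- fuseNetworks(s$stack, sel)
    trace <- oracle_prefix_trace(s$stack, mainRois(sel), suppRois(sel))
    expect_equal(pvalueTrace(fus), trace, tolerance = 1e-10)
    expect_identical(fusedIndex(fus), which.min(trace) - 1L)
    expect_equal(fusedPvalue(fus), min(trace), tolerance = 1e-10)
  }
})

test_that("the fused network never scores worse than the main network alone", {
  for (seed in 1:5) {
    s <- small_sim(seed = seed, nSubjects = 4L, nRois = 12L, nTime = 30L,
                   instanceSizes = c(3L, 4L, 3L, 2L))
    sel <- selectMain(s$stack, s$sim$instances)
    fus <- fuseNetworks(s$stack, sel)
    expect_lte(fusedPvalue(fus), pvalueTrace(fus)[1])
    expect_equal(length(fusedRois(fus)),
                 length(mainRois(sel)) + fusedIndex(fus))
  }
})

test_that("selection and fusion are deterministic", {
  s <- small_sim(seed = 77, nSubjects = 4L, nRois = 12L, nTime = 30L,
                 instanceSizes = c(3L, 4L, 3L, 2L))
  sel1 <- selectMain(s$stack, s$sim$instances)
  sel2 <- selectMain(s$stack, s$sim$instances)
  expect_identical(suppRois(sel1), suppRois(sel2))
  expect_identical(instancePvalues(sel1), instancePvalues(sel2))
  fus1 <- fuseNetworks(s$stack, sel1)
  fus2 <- fuseNetworks(s$stack, sel2)
  expect_identical(fusedRois(fus1), fusedRois(fus2))
  expect_identical(pvalueTrace(fus1), pvalueTrace(fus2))
})

test_that("an external supplementary ordering drives the same prefix search", {
  s <- small_sim(seed = 19, nSubjects = 4L, nRois = 12L, nTime = 30L,
                 instanceSizes = c(3L, 4L, 3L, 2L))
  sel <- selectMain(s$stack, s$sim$instances)
  ext <- rev(suppRois(sel))
  fus <- fuseNetworks(s$stack, sel, suppOrder = ext)
  trace <- oracle_prefix_trace(s$stack, mainRois(sel), ext)
  expect_equal(pvalueTrace(fus), trace, tolerance = 1e-10)
  expect_identical(fusedRois(fus),
                   c(mainRois(sel), head(ext, fusedIndex(fus))))
  expect_error(fuseNetworks(s$stack, sel, suppOrder = ext[-1]),
               "permutation")
})

test_that("the run report conserves counts and round-trips through JSON", {
  s <- small_sim(seed = 23)
  sel <- selectMain(s$stack, s$sim$instances)
  fus <- fuseNetworks(s$stack, sel)
  rep <- fusionReport(sel, fus, s$stack)
  expect_equal(sum(unlist(rep$fusedByLobe)), rep$fusedSize)
  expect_equal(sum(unlist(rep$fusedByAtlas)), rep$fusedSize)
  expect_equal(rep$fusedSize, length(mainRois(sel)) + rep$fusedIndex)
  expect_equal(nrow(rep$priority), length(suppRois(sel)))

  tf <- withr::local_tempfile(fileext = ".json")
  writeFusionReport(rep, tf)
  back <- readFusionReport(tf)
  expect_equal(back$mainInstance, rep$mainInstance)
  expect_equal(back$fusedIndex, rep$fusedIndex)
  expect_equal(back$pvalueTrace, rep$pvalueTrace, tolerance = 1e-12)
  expect_equal(as.data.frame(back$priority), rep$priority,
               tolerance = 1e-12)
  expect_equal(unlist(back$fusedByLobe), unlist(rep$fusedByLobe))

  dir <- withr::local_tempdir()
  writeReportTables(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("priority.tsv", "trace.tsv",
                                               "instances.tsv")))))
  tr <- utils::read.delim(file.path(dir, "trace.tsv"))
  expect_equal(tr$pvalue, rep$pvalueTrace, tolerance = 1e-6)
})
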