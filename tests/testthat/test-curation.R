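test_that("effect inference follows the modulation-direction rule and is antisymmetric", {
  # full enumeration of the mapping
  expect_equal(infer_effect("decrease", "detrimental"), "protective")
  expect_equal(infer_effect("decrease", "protective"), "detrimental")
  expect_equal(infer_effect("increase", "protective"), "protective")
  expect_equal(infer_effect("increase", "detrimental"), "detrimental")
  for (act in c("increase", "decrease")) {
    expect_equal(infer_effect(act, "no_effect"), "no_effect")
    expect_equal(infer_effect(act, "mixed"), "mixed")
  }
  # flipping the modulation direction flips directional inferences
  for (obs in c("protective", "detrimental")) {
    a <- infer_effect("increase", obs)
    b <- infer_effect("decrease", obs)
    expect_true(a != b)
    expect_setequal(c(a, b), c("protective", "detrimental"))
  }
  expect_error(infer_effect("up", "protective"), "activity_change")
  expect_error(infer_effect("increase", "better"), "observed_effect")
})

test_that("consensus combines effects with supersede and ambiguity rules", {
  expect_equal(consensus_effect(c("protective", "protective", "no_effect")),
               "protective")
  expect_equal(consensus_effect(c("detrimental", "protective")), "ambiguous")
  expect_equal(consensus_effect(c("no_effect", "no_effect")), "no_effect")
  expect_equal(consensus_effect(c("no_effect", "mixed")), "mixed")
  expect_equal(consensus_effect(c("mixed", "detrimental")), "detrimental")
  expect_error(consensus_effect(character()), "empty")

  # permutation-invariant and idempotent under duplication
  set.seed(11)
  for (i in 1:25) {
    eff <- sample(c("protective", "detrimental", "no_effect", "mixed"),
                  sample(1:6, 1), replace = TRUE)
    base <- consensus_effect(eff)
    expect_equal(consensus_effect(sample(eff)), base)
    expect_equal(consensus_effect(rep(eff, 3)), base)
  }
})

test_that("observation reader parses, normalises and validates rows", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tpmid\tintervention\tactivity_change\tapproach\tmodel\tobserved_effect\tspecificity\tspecies",
    "ttr \t28941045\tKnockout\tdecrease\tgenetic\tSurgical - DMM\tDetrimental\tGlobal\tMouse"
  ), tmp)
  obs <- read_observations(tmp)
  expect_s3_class(obs, "oa_observations")
  expect_equal(obs$gene, "TTR")            # uppercased, trimmed
  expect_equal(obs$model, "surgical")
  expect_equal(obs$model_subtype, "dmm")
  expect_equal(obs$observed_effect, "detrimental")

  # header-only file -> zero rows, full schema
  writeLines("gene\tpmid\tintervention\tactivity_change\tapproach\tmodel\tobserved_effect",
             tmp)
  expect_equal(nrow(read_observations(tmp)), 0L)

  # enum violation is a row-level error naming the row
  writeLines(c(
    "gene\tpmid\tintervention\tactivity_change\tapproach\tmodel\tobserved_effect",
    "A\t1\tKnockout\tdecrease\tgenetic\tsurgical\tdetrimental",
    "B\t2\tKnockout\tdecrease\tgenetic\tsurgical\tbetter"
  ), tmp)
  expect_error(read_observations(tmp), "observed_effect.*2")

  # missing mandatory column names the column
  writeLines(c("gene\tpmid\tmodel\tobserved_effect", "A\t1\tsurgical\tprotective"),
             tmp)
  expect_error(read_observations(tmp), "intervention")
})

test_that("activity and approach fall back to the intervention map", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c(
    "gene,pmid,intervention,model,observed_effect",
    "A,1,Knockout,surgical,detrimental",
    "B,2,Overexpression,spontaneous,protective",
    "C,3,SomeDrug123,chemical,protective"
  ), tmp)
  expect_error(read_observations(tmp), "activity_change.*3")
  writeLines(c(
    "gene,pmid,intervention,model,observed_effect",
    "A,1,Knockout,surgical,detrimental",
    "B,2,Overexpression,spontaneous,protective"
  ), tmp)
  obs <- read_observations(tmp)
  expect_equal(obs$activity_change, c("decrease", "increase"))
  expect_equal(obs$approach, c("genetic", "genetic"))
})

test_that("consistency report counts strata as defined", {
  # A: two agreeing genetic; B: conflicting genetic; C: single genetic
  obs <- make_obs(gene = c("A", "A", "B", "B", "C"),
                  activity = c("decrease", "decrease", "decrease", "increase", "decrease"),
                  observed = "detrimental")
  cr <- consistency_report(obs)
  expect_equal(unname(cr$genetic_multi), c(1L, 2L))
  expect_equal(unname(cr$exogenous_multi), c(0L, 0L))

  # agreeing genetic and exogenous consensus counts as cross-approach consistent
  obs2 <- make_obs(gene = c("S", "S"), approach = c("genetic", "exogenous"),
                   activity = c("decrease", "increase"),
                   observed = c("detrimental", "protective"))
  cr2 <- consistency_report(obs2)
  expect_equal(unname(cr2$cross_approach), c(1L, 1L))

  # genes with only no-effect observations are consistent; mixed is excluded
  obs3 <- make_obs(gene = c("N", "N", "M", "M", "M"),
                   observed = c("no_effect", "no_effect", "mixed", "mixed",
                                "no_effect"))
  cr3 <- consistency_report(obs3)
  expect_equal(unname(cr3$genetic_multi), c(2L, 2L))

  # cross-model: ambiguous-within-model genes are excluded from the total
  obs4 <- make_obs(gene = c("X", "X", "Y", "Y", "Y"),
                   model = c("spontaneous", "surgical",
                             "spontaneous", "spontaneous", "surgical"),
                   activity = c("decrease", "decrease",
                                "decrease", "increase", "decrease"),
                   observed = "detrimental")
  cr4 <- consistency_report(obs4)
  expect_equal(unname(cr4$cross_model), c(1L, 1L))  # Y ambiguous in spontaneous

  empty <- synth_observations(n_genes = 0L)$observations
  expect_equal(unname(consistency_report(empty)$cross_model), c(0L, 0L))
})

test_that("cross-approach flag switches between consensus and pooled comparison", {
  # genetic: protective, protective; exogenous: protective, detrimental
  # per-approach consensus: protective vs ambiguous -> inconsistent
  # pooled observations contain both directions -> inconsistent too
  # but genetic={protective}, exogenous={protective} agree when the
  # conflicting exogenous row is removed
  obs <- make_obs(gene = rep("G", 4),
                  approach = c("genetic", "genetic", "exogenous", "exogenous"),
                  activity = "decrease",
                  observed = c("detrimental", "detrimental", "detrimental",
                               "protective"))
  expect_equal(unname(consistency_report(obs)$cross_approach), c(0L, 1L))
  expect_equal(unname(consistency_report(
    obs, cross_approach_method = "observations")$cross_approach), c(0L, 1L))
  # no-effect exogenous observation superseded under consensus comparison,
  # but pooling only looks at directions, so both methods agree here
  obs2 <- make_obs(gene = rep("H", 3),
                   approach = c("genetic", "exogenous", "exogenous"),
                   activity = "decrease",
                   observed = c("detrimental", "detrimental", "no_effect"))
  expect_equal(unname(consistency_report(obs2)$cross_approach), c(1L, 1L))
})

test_that("corpus summary counts publications, genes and models", {
  one <- make_obs("A")
  sc <- summary_counts(one)
  expect_equal(sc$n_publications, 1L)
  expect_equal(sc$n_unique_genes, 1L)
  expect_equal(sc$n_genetic_observations, 1L)

  # same gene + pmid, two models: one publication, one gene, two model counts
  two <- make_obs(c("A", "A"), model = c("surgical", "spontaneous"),
                  pmid = "P1")
  sc2 <- summary_counts(two)
  expect_equal(sc2$n_unique_genes, 1L)
  expect_equal(sc2$n_publications, 1L)
  expect_equal(sc2$per_model_counts$surgical, 1L)
  expect_equal(sc2$per_model_counts$spontaneous, 1L)
  expect_equal(sc2$per_gene_study_counts$A, 1L)
})

test_that("gene summaries aggregate observation, approach and publication counts", {
  obs <- make_obs(gene = c("A", "A", "A", "B"),
                  approach = c("genetic", "genetic", "exogenous", "genetic"),
                  activity = "decrease",
                  observed = c("detrimental", "no_effect", "detrimental",
                               "protective"),
                  pmid = c("P1", "P1", "P2", "P3"))
  gs <- gene_summaries(obs)
  a <- gs[gs$gene == "A", ]
  expect_equal(a$consensus, "protective")
  expect_equal(a$n_genetic, 2L)
  expect_equal(a$n_exogenous, 1L)
  expect_equal(a$n_publications, 2L)
  expect_equal(gs[gs$gene == "B", ]$consensus, "detrimental")
})
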