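test_that("anatomy realization is deterministic without noise and encodes the aging shapes", {
  traj <- default_trajectories()
  for (q in names(traj)) traj[[q]]$sd <- 0
  s1 <- anatomy_at_age(40, traj)
  s2 <- anatomy_at_age(40, traj)
  expect_identical(s1, s2)

  th_at <- function(age) tesfield:::phantom_thicknesses_mm(anatomy_at_age(age, traj))
  # skull inverted-U peaking at 60
  expect_gte(th_at(60)[["SKULL"]], th_at(20)[["SKULL"]])
  expect_gte(th_at(60)[["SKULL"]], th_at(88)[["SKULL"]])
  # CSF rises after 20
  expect_gte(th_at(80)[["CSF"]], th_at(25)[["CSF"]])
  # scalp stable to 60 then declining
  expect_equal(th_at(60)[["SCALP"]], th_at(25)[["SCALP"]], tolerance = 1e-12)
  expect_lt(th_at(85)[["SCALP"]], th_at(60)[["SCALP"]])
  # GM declines; ventricles grow
  expect_lt(th_at(88)[["GM"]], th_at(20)[["GM"]])
  expect_gt(th_at(88)[["VENTRICLE"]], th_at(30)[["VENTRICLE"]])

  expect_error(anatomy_at_age(10, traj), "age")
})

test_that("cohort sampling reproduces the decade-group design deterministically", {
  n_table1 <- c(7L, 49L, 76L, 79L, 73L, 72L, 84L, 36L)
  cohort <- cohort_spec(n_per_group = n_table1, seed = 11L)
  subj <- sample_cohort(cohort)
  expect_equal(nrow(subj), 476L)
  expect_equal(
    as.integer(table(factor(subj$group, levels = age_group_bins()$group))),
    n_table1
  )
  # every age inside its bin
  bins <- age_group_bins()
  for (g in seq_len(nrow(bins))) {
    a <- subj$age[subj$group == bins$group[g]]
    expect_true(all(a >= bins$lo[g] & a < bins$hi[g] + 1))
  }
  # bit-identical under the same master seed, different under another
  subj2 <- sample_cohort(cohort)
  expect_identical(subj$age, subj2$age)
  expect_identical(subj$skull_mm, subj2$skull_mm)
  subj3 <- sample_cohort(cohort_spec(n_per_group = n_table1, seed = 12L))
  expect_false(identical(subj$age, subj3$age))
})

test_that("realized group-mean thickness converges to the trajectory (SE ~ 1/sqrt(n))", {
  cohort <- cohort_spec(
    n_per_group = ifelse(seq_len(8L) == 2L, 200L, 1L), seed = 5L
  )
  subj <- sample_cohort(cohort)
  g2 <- subj[subj$group == "21-30", ]
  traj <- default_trajectories()
  expected <- mean(vapply(g2$age, function(a) {
    tesfield:::eval_trajectory(traj$skull, a)
  }, numeric(1L)))
  se <- traj$skull$sd / sqrt(nrow(g2))
  expect_equal(nrow(g2), 200L)
  expect_lt(abs(mean(g2$skull_mm) - expected), 4 * se)
})

test_that("phantom ROI analogs sit where the anatomy dictates", {
  mesh <- smoke_mesh()
  rois <- define_phantom_rois(mesh)
  expect_true(all(lengths(rois) > 0L))
  # cortical cones disjoint
  expect_length(intersect(rois$VMPFC_A, rois$PPC_A), 0L)
  # hippocampal analog on the left (-x)
  cen <- tesfield:::tet_centroids(mesh)
  expect_lt(mean(cen[rois$HIPP_A, 1L]), 0)
  # prefrontal analog anterior-inferior, parietal analog posterior-superior
  expect_gt(mean(cen[rois$VMPFC_A, 2L]), 0)
  expect_lt(mean(cen[rois$VMPFC_A, 3L]), 0)
  expect_lt(mean(cen[rois$PPC_A, 2L]), 0)
  expect_gt(mean(cen[rois$PPC_A, 3L]), 0)
  # ROI volumes positive
  for (ids in rois) expect_gt(sum(mesh$volume[ids]), 0)
})

test_that("degenerate and single-layer phantom specs behave", {
  expect_error(phantom_spec(r_vent = 0.07), "ventricle")
  expect_error(phantom_spec(r_skull = 0.095), "decreasing")
  # single-compartment sphere: every element SCALP
  one <- structure(
    list(radii = 0.05, labels = "SCALP"),
    class = "phantom_spec"
  )
  mesh <- build_layered_sphere(one, subdiv = 1L, h = 1e-2)
  expect_true(all(mesh$tissue == "SCALP"))
  v <- validate_mesh(mesh)
  expect_length(v$violations, 0L)
})
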