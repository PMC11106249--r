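de_tab <- function(genes, dirs, analysis = "x") {
  lfc <- ifelse(dirs == "up", 2, ifelse(dirs == "down", -2, 0))
  fdr <- ifelse(dirs == "ns", 0.9, 0.01)
  data.frame(gene_id = genes, analysis_id = analysis, log2fc = lfc,
             pvalue = fdr / 2, fdr = fdr, direction = dirs,
             stringsAsFactors = FALSE)
}

test_that("within-species filter removes same-direction control signals", {
  genes <- c("A", "B", "C", "D")
  tests <- list(horn_2mo = de_tab(genes, c("up", "up", "down", "ns")))
  controls <- list(skin = de_tab(genes, c("ns", "up", "up", "up")))
  prof <- within_species_distinct(tests, controls)
  expect_identical(prof$horn_2mo[prof$gene_id == "A"], "up")       # retained
  expect_identical(prof$horn_2mo[prof$gene_id == "B"], "ns")       # removed
  expect_identical(prof$horn_2mo[prof$gene_id == "C"], "down")     # opposite
  exc <- attr(prof, "exclusions")
  expect_identical(exc$gene_id, "B")
  expect_identical(exc$reason, "excluded_within_species_control")
  flg <- attr(prof, "control_flags")
  expect_identical(flg$gene_id, "C")
  expect_match(flg$flag, "opposite_direction_in_skin")

  expect_error(within_species_distinct(tests, controls,
                                       required_controls = c("skin", "bone")),
               "bone")
})

test_that("homology calls follow the outgroup-conditioned rule", {
  genes <- c("PLAIN", "RXFP2L", "TNRC6L", "ONESIDE")
  tests_a <- list(horn_4mo = de_tab(genes, c("up", "up", "down", "up")))
  ctl_a <- list(skin = de_tab(genes, c("ns", "ns", "ns", "ns")))
  tests_b <- list(pre_cartilage = de_tab(genes, c("up", "up", "down", "ns")),
                  pedicle = de_tab(genes, c("ns", "up", "down", "ns")))
  ctl_b <- list(skin = de_tab(genes, rep("ns", 4)),
                bone = de_tab(genes, c("ns", "ns", "up", "ns")))
  outg <- list(skin = de_tab(genes, c("ns", "up", "ns", "ns")),
               cartilage_control = de_tab(genes, rep("ns", 4)),
               bone = de_tab(genes, rep("ns", 4)))
  prof_a <- within_species_distinct(tests_a, ctl_a)
  prof_b <- within_species_distinct(tests_b, ctl_b)
  calls <- call_homology(prof_a, prof_b, outg)

  # up in horn and antler, ns in every pig tissue
  expect_identical(calls$status[calls$gene_id == "PLAIN"], "homologous")
  # shared signal but also up in pig skin
  expect_identical(calls$status[calls$gene_id == "RXFP2L"],
                   "excluded_outgroup")
  # down in horn/antler, up in deer bone (opposite direction): homologous
  # with a control flag recording the reversed bone signal
  tn <- calls[calls$gene_id == "TNRC6L", ]
  expect_identical(tn$status, "homologous")
  expect_identical(tn$shared_direction, "down")
  expect_match(tn$control_flags, "opposite_direction_in_bone")
  expect_identical(tn$antler_support, "pre_cartilage,pedicle")
  expect_identical(calls$status[calls$gene_id == "ONESIDE"], "not_shared")

  # without any outgroup table every candidate is untestable
  calls0 <- call_homology(prof_a, prof_b, list())
  expect_true(all(calls0$status[calls0$gene_id != "ONESIDE"] ==
                    "untestable_missing_outgroup"))
})

test_that("homology decisions match the exhaustive truth-table oracle", {
  lv <- c("up", "down", "ns", "absent")
  combos <- expand.grid(a1 = lv, a2 = lv, b1 = lv, b2 = lv, o1 = lv,
                        o2 = lv, stringsAsFactors = FALSE)
  genes <- sprintf("G%05d", seq_len(nrow(combos)))
  prof_a <- data.frame(gene_id = genes, x1 = combos$a1, x2 = combos$a2,
                       stringsAsFactors = FALSE)
  prof_b <- data.frame(gene_id = genes, y1 = combos$b1, y2 = combos$b2,
                       stringsAsFactors = FALSE)
  out_tabs <- list(skin = de_tab(genes, combos$o1, "skin"),
                   bone = de_tab(genes, combos$o2, "bone"))
  out_tabs$skin <- out_tabs$skin[combos$o1 != "absent", ]
  out_tabs$bone <- out_tabs$bone[combos$o2 != "absent", ]
  calls <- call_homology(prof_a, prof_b, out_tabs)

  expected <- vapply(seq_len(nrow(combos)), function(i)
    homology_oracle(c(combos$a1[i], combos$a2[i]),
                    c(combos$b1[i], combos$b2[i]),
                    c(combos$o1[i], combos$o2[i])), "")
  has_row <- !is.na(expected)
  expect_setequal(calls$gene_id, genes[has_row])
  got <- calls$status[match(genes[has_row], calls$gene_id)]
  expect_identical(got, unname(expected[has_row]))
})

test_that("outgroup evidence and extra support act monotonically", {
  lv <- c("up", "down", "ns", "absent")
  combos <- expand.grid(a1 = lv, b1 = lv, o1 = lv, stringsAsFactors = FALSE)
  genes <- sprintf("G%03d", seq_len(nrow(combos)))
  prof_a <- data.frame(gene_id = genes, x1 = combos$a1,
                       stringsAsFactors = FALSE)
  prof_b <- data.frame(gene_id = genes, y1 = combos$b1,
                       stringsAsFactors = FALSE)
  with_out <- call_homology(prof_a, prof_b,
                            list(skin = de_tab(genes, combos$o1, "skin")))
  no_out <- call_homology(prof_a, prof_b, list())
  # removing the outgroup can only make calls untestable, never homologous
  expect_false(any(no_out$status == "homologous"))

  # adding an agreeing ingroup analysis never shrinks support or flips a
  # homologous call to not_shared
  prof_b2 <- prof_b
  prof_b2$y2 <- prof_b$y1
  with_more <- call_homology(prof_a, prof_b2,
                             list(skin = de_tab(genes, combos$o1, "skin")))
  m <- match(with_out$gene_id, with_more$gene_id)
  expect_false(any(with_out$status == "homologous" &
                     with_more$status[m] == "not_shared"))
  hom <- which(with_out$status == "homologous")
  expect_true(all(nchar(with_more$antler_support[m[hom]]) >=
                    nchar(with_out$antler_support[hom])))
})

test_that("tau homology follows specificity, control and outgroup rules", {
  mk_tau <- function(genes, strict, relaxed, ctl) {
    data.frame(gene_id = genes, taxon = "t", tau = 0.95,
               strict_tissue = strict, relaxed_tissues = relaxed,
               control_specific = ctl, stringsAsFactors = FALSE)
  }
  genes <- c("RXFP2L", "LONELY", "SKINNY")
  tau_a <- mk_tau(genes, c("horn_bud_2mo", "horn_bud_2mo", "horn_bud_2mo"),
                  c("horn_bud_2mo", "horn_bud_2mo", "horn_bud_2mo,skin"),
                  c(FALSE, FALSE, TRUE))
  tau_b <- mk_tau(genes, c("reserve_mesenchyme", NA, "pedicle"),
                  c("reserve_mesenchyme", "", "pedicle"),
                  c(FALSE, FALSE, FALSE))
  tau_o <- mk_tau("OTHER", "skin", "skin", TRUE)
  app_a <- c("horn_bud_2mo", "horn_bud_4mo")
  app_b <- c("pedicle", "antler_tip", "reserve_mesenchyme")

  strict <- tau_homology(tau_a, tau_b, tau_o, "strict", app_a, app_b)
  expect_identical(strict$status[strict$gene_id == "RXFP2L"], "homologous")
  expect_identical(strict$horn_support[strict$gene_id == "RXFP2L"],
                   "horn_bud_2mo")
  expect_identical(strict$antler_support[strict$gene_id == "RXFP2L"],
                   "reserve_mesenchyme")
  expect_identical(strict$status[strict$gene_id == "LONELY"], "not_shared")
  expect_identical(strict$status[strict$gene_id == "SKINNY"],
                   "excluded_within_species_control")

  # outgroup specificity excludes at the matching threshold
  tau_o2 <- mk_tau("RXFP2L", "skin", "skin", TRUE)
  strict2 <- tau_homology(tau_a, tau_b, tau_o2, "strict", app_a, app_b)
  expect_identical(strict2$status[strict2$gene_id == "RXFP2L"],
                   "excluded_outgroup")

  relaxed <- tau_homology(tau_a, tau_b, tau_o, "relaxed", app_a, app_b)
  expect_identical(relaxed$status[relaxed$gene_id == "SKINNY"],
                   "excluded_within_species_control")
  expect_error(tau_homology(tau_a, tau_b, tau_o, "loose", app_a, app_b))
})

test_that("shared proportions reproduce the published relaxed-table rows", {
  fx <- fixture_tables()
  calls <- fixture_homology_calls(fx$relaxed)
  antler <- c("pedicle", "antler_tip", "mineralized_cartilage",
              "cartilage_zone", "transition_zone", "pre_cartilage",
              "reserve_mesenchyme")
  prop <- shared_proportions(calls, c("horn_2mo", "horn_4mo"), antler)
  p2 <- prop[prop$horn_analysis == "horn_2mo", ]
  p4 <- prop[prop$horn_analysis == "horn_4mo", ]
  expect_equal(unique(p2$total), 18)
  expect_equal(unique(p4$total), 30)
  expect_equal(round(p2$proportion[match(antler, p2$antler_tissue)], 2),
               c(0.61, 0.67, 0.33, 0.44, 0.50, 0.56, 0.61))
  expect_equal(round(p4$proportion[match(antler, p4$antler_tissue)], 2),
               c(0.27, 0.37, 0.30, 0.37, 0.53, 0.43, 0.33))
  expect_equal(p2$shared_count[p2$antler_tissue == "antler_tip"], 12)
  expect_equal(p4$shared_count[p4$antler_tissue == "transition_zone"], 16)

  empty <- shared_proportions(calls[0, ], "horn_2mo", antler)
  expect_true(all(is.na(empty$proportion)))
})

test_that("fixture tables carry the published structure", {
  fx <- fixture_tables()
  expect_equal(nrow(fx$strict), 9)
  expect_equal(nrow(fx$relaxed), 41)
  horn <- c("horn_2mo", "horn_4mo")
  deer <- setdiff(names(fx$relaxed), c("gene", horn))
  for (tab in fx) {
    expect_true(all(rowSums(tab[horn]) >= 1))
    expect_true(all(rowSums(tab[setdiff(names(tab), c("gene", horn))]) >= 1))
  }
  chek1 <- fx$relaxed[fx$relaxed$gene == "CHEK1", ]
  expect_equal(sum(chek1[-1]), 8)
  expect_equal(sum(chek1[horn]), 2)   # spans both horn-bud ages
  rxfp2 <- fx$strict[fx$strict$gene == "RXFP2", ]
  expect_equal(rxfp2$horn_2mo, 1)
  expect_equal(rxfp2$reserve_mesenchyme, 1)
  expect_equal(sum(rxfp2[-1]), 2)
})

test_that("reports are deterministic and reproduce the fixtures", {
  fx <- fixture_tables()
  calls <- list(tau_strict = fixture_homology_calls(fx$strict, "tau_strict"),
                tau_relaxed = fixture_homology_calls(fx$relaxed))
  antler <- setdiff(names(fx$strict), c("gene", "horn_2mo", "horn_4mo"))
  props <- list(tau_relaxed = shared_proportions(calls$tau_relaxed,
                                                 c("horn_2mo", "horn_4mo"),
                                                 antler))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  build_report(calls, props, path = p1)
  build_report(calls, props, path = p2)
  expect_identical(readLines(p1), readLines(p2))

  rep <- build_report(calls, props)
  expect_equal(rep$homology$tau_strict$n_homologous, 9)
  expect_equal(rep$homology$tau_relaxed$n_homologous, 41)
  expect_setequal(vapply(rep$homology$tau_strict$genes, `[[`, "",
                         "gene_id"),
                  c("NCAM2", "SCG2", "DMP1", "RXFP2", "SFRP2", "GAD2",
                    "TMEM211", "TMIE", "TYR"))
})
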