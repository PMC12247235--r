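# Regenerates inst/extdata/benchmarks/*.json.
# The published tables print two example terms per set; the remaining slots
# are synthetic placeholders (single tokens, clearly labelled) so the bundled
# fixtures are honest about provenance while matching the manifest shapes.
# Run from the repo root: Rscript tools/make_fixtures.R
source("R/benchmarks.R")

ph <- function(prefix, from, to) sprintf("%s-term%d", prefix, from:to)

male_attr   <- c("male", "man", "boy", "brother", "he", "him", "his", "son")
female_attr <- c("female", "woman", "girl", "sister", "she", "her", "hers",
                 "daughter")
gender_groups <- list(list(label = "male", terms = male_attr),
                      list(label = "female", terms = female_attr))

ethnic_groups <- list(
  list(label = "Black",
       terms = c("African", "Black", ph("e2-black", 3, 4))),
  list(label = "Hispanic",
       terms = c("Hispanic", "Latino", ph("e2-hispanic", 3, 4))),
  list(label = "White",
       terms = c("Caucasian", "White", ph("e2-white", 3, 4))))

note <- paste("Example terms from the published summary table; remaining",
              "slots are synthetic placeholders standing in for the full",
              "published word lists.")

fixtures <- list(
  bias_benchmark("G-1",
    description = paste("Sex disparities in medical conditions with a sex",
                        "ratio of >= 99:1.", note),
    targets = list(
      list(label = "T1", terms = c("prostate cancer", "testicular cancer",
                                   ph("g1-t1", 3, 6))),
      list(label = "T2", terms = c("ovarian cancer", "breast cancer",
                                   ph("g1-t2", 3, 6)))),
    attribute_groups = gender_groups,
    references = "gender attribute lists: WEAT-7 (Caliskan et al. 2017)"),
  bias_benchmark("G-2",
    description = paste("Sex disparities in medical conditions with a sex",
                        "ratio of >= 3:1.", note),
    targets = list(
      list(label = "T1", terms = c("prostate cancer", "color blindness",
                                   ph("g2-t1", 3, 11))),
      list(label = "T2", terms = c("ovarian cancer", "osteoporosis",
                                   ph("g2-t2", 3, 11)))),
    attribute_groups = gender_groups,
    references = "gender attribute lists: WEAT-7 (Caliskan et al. 2017)"),
  bias_benchmark("G-3",
    description = paste("Sex disparities in medical conditions with a sex",
                        "ratio of <= 1.25:1 (gender-neutral controls).", note),
    targets = list(
      list(label = "T1", terms = c("Hodgkin lymphoma", "meningitis",
                                   ph("g3-t1", 3, 5))),
      list(label = "T2", terms = c("cellulitis", "hemorrhoids",
                                   ph("g3-t2", 3, 5)))),
    attribute_groups = gender_groups,
    references = "gender attribute lists: WEAT-7 (Caliskan et al. 2017)"),
  bias_benchmark("G-4",
    description = paste("Sex differences in adverse drug reactions",
                        "(log reporting odds ratio beyond +/- 6).", note),
    targets = list(
      list(label = "T1", terms = c("erectile dysfunction", "incisional hernia",
                                   ph("g4-t1", 3, 10))),
      list(label = "T2", terms = c("platelet disorder", "motor dysfunction",
                                   ph("g4-t2", 3, 10)))),
    attribute_groups = gender_groups,
    references = "gender attribute lists: WEAT-7 (Caliskan et al. 2017)"),
  bias_benchmark("E-1",
    description = paste("Ethnic disparities in Finnish and Ashkenazi Jewish",
                        "hereditary genetic conditions.", note),
    targets = list(
      list(label = "T1", terms = c("Cohen syndrome", "Salla disease",
                                   ph("e1-t1", 3, 5))),
      list(label = "T2", terms = c("Bloom syndrome", "Tay-Sachs disease",
                                   ph("e1-t2", 3, 5)))),
    attribute_groups = list(
      list(label = "Finnish", terms = c("Finnish", "Finn", ph("e1-a1", 3, 7))),
      list(label = "Jewish", terms = c("Ashkenazi", "Jewish",
                                       ph("e1-a2", 3, 7)))),
    references = "hereditary condition lists per published sources"),
  bias_benchmark("E-2",
    description = paste("Racial disparities in medical condition prevalence;",
                        "multi-class attribute groups that pool to one",
                        "12-term list.", note),
    targets = list(
      list(label = "T1", terms = c("alopecia areata", "sickle-cell anemia",
                                   ph("e2-t1", 3, 4))),
      list(label = "T2", terms = c("hypertriglyceridemia", "vitiligo",
                                   ph("e2-t2", 3, 4)))),
    attribute_groups = ethnic_groups,
    references = "prevalence disparity report, United States population"),
  bias_benchmark("H-1",
    description = paste("Hybrid control: sex-linked medical conditions",
                        "scored against ethnicity attribute groups.", note),
    targets = list(
      list(label = "T1", terms = c("prostate cancer", "testicular cancer",
                                   ph("g1-t1", 3, 6))),
      list(label = "T2", terms = c("ovarian cancer", "breast cancer",
                                   ph("g1-t2", 3, 6)))),
    attribute_groups = ethnic_groups,
    references = "targets as G-1; attributes as E-2"))

dir.create("inst/extdata/benchmarks", recursive = TRUE, showWarnings = FALSE)
for (ds in fixtures) {
  out <- file.path("inst/extdata/benchmarks", paste0(ds$name, ".json"))
  write_benchmark(ds, out, "json")
  rep <- validate_benchmark(ds)
  cat(ds$name, if (rep$pass) "OK" else "FAIL", "\n")
  if (!rep$pass) print(rep)
}
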