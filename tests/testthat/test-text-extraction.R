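test_that("lexicon classes must be disjoint and triggers non-empty", {
  expect_error(
    qualifier_lexicon(increase_phrases = c("elevated"),
                      high_increase_phrases = c("elevated", "greatly elevated"),
                      decrease_phrases = "decreased",
                      high_decrease_phrases = "greatly decreased"),
    "disjoint")
  expect_error(
    qualifier_lexicon("a", "b", "c", "d", trigger_substrings = character()),
    "non-empty")
  expect_equal(delta_sign(c("increase", "high_increase",
                            "decrease", "high_decrease")),
               c(1L, 1L, -1L, -1L))
  expect_error(delta_sign("sideways"), "unknown delta")
})

test_that("sentence splitting handles terminators, abbreviations and mentions", {
  s <- split_sentences("A is high. B is low.")
  expect_equal(nrow(s), 2L)
  expect_equal(trimws(s$text), c("A is high.", "B is low."))
  # spans partition the text
  expect_equal(s$start[1], 0L)
  expect_equal(s$end[2], nchar("A is high. B is low."))
  expect_equal(s$start[-1], s$end[-nrow(s)])

  s2 <- split_sentences(
    "Infection with E. coli was studied. Levels rose afterwards.")
  expect_equal(nrow(s2), 2L)
  expect_match(s2$text[1], "E. coli", fixed = TRUE)

  s3 <- split_sentences("a single sentence without terminal punctuation")
  expect_equal(nrow(s3), 1L)
  expect_equal(s3$start, 0L)

  # boundary inside an entity mention span is suppressed
  txt <- "Binding of SNF1. TG22 was produced."
  doc <- annotated_document("1", txt, "",
    data.frame(start = 11L, end = 20L, text = "SNF1. TG22",
               type = "Gene", id = "TG22"))
  expect_equal(nrow(split_sentences(doc)), 1L)
  # the same text without the mention does split
  expect_equal(nrow(split_sentences(txt)), 2L)
})

test_that("trigger detection matches substrings case-insensitively", {
  lex <- default_lexicon()
  expect_true(detect_trigger("Overexpression of X was seen.", lex))
  expect_true(detect_trigger("The protein is produced by stromal cells.", lex))
  expect_true(detect_trigger("TRANSCRIPTION of the locus rose.", lex))
  expect_false(detect_trigger("X levels correlate with Y severity", lex))
})

test_that("delta classification is longest-match with exclusion handling", {
  lex <- default_lexicon()
  expect_equal(classify_delta("expression was greatly elevated here", lex)$delta,
               "high_increase")
  expect_equal(classify_delta("it was significantly overexpressed", lex)$delta,
               "increase")
  expect_equal(classify_delta("it was elevated", lex)$delta, "increase")
  r <- classify_delta("we observed aberrant expression of the gene", lex)
  expect_true(is.na(r$delta))
  expect_equal(r$reason, "excluded")
  r2 <- classify_delta("the gene expression was measured", lex)
  expect_equal(r2$reason, "no_qualifier")
})

test_that("tri-occurrence extraction needs gene, disease and trigger in one sentence", {
  doc <- make_doc("100", "A report.",
    "Expression of TP53 was elevated in patients with psoriasis.",
    genes = list("TP53"), diseases = list("psoriasis"))
  st <- extract_statements(list(doc))
  expect_equal(nrow(st), 1L)
  expect_equal(st$gene, "TP53")
  expect_equal(st$disease, "psoriasis")
  expect_equal(st$delta, "increase")

  # gene and disease in different sentences: no statement
  doc2 <- make_doc("101", "A report.",
    "Expression of TP53 was elevated in tissue. The cohort had psoriasis.",
    genes = list("TP53"), diseases = list("psoriasis"))
  expect_equal(nrow(extract_statements(list(doc2))), 0L)

  # no trigger word: no statement
  doc3 <- make_doc("102", "A report.",
    "TP53 was elevated in patients with psoriasis.",
    genes = list("TP53"), diseases = list("psoriasis"))
  expect_equal(nrow(extract_statements(list(doc3))), 0L)
})

test_that("redundant tuples are deduplicated and ambiguous genes dropped", {
  dup_sentence <- "Expression of TP53 was elevated in patients with psoriasis."
  doc <- make_doc("103", "A report.",
                  paste(dup_sentence, dup_sentence),
                  genes = list(), diseases = list())
  # annotate both occurrences of gene and disease by hand
  pos_g <- gregexpr("TP53", doc$text, fixed = TRUE)[[1]]
  pos_d <- gregexpr("psoriasis", doc$text, fixed = TRUE)[[1]]
  m <- rbind(
    data.frame(start = as.integer(pos_g) - 1L,
               end = as.integer(pos_g) + 3L, text = "TP53", type = "Gene",
               id = "TP53"),
    data.frame(start = as.integer(pos_d) - 1L,
               end = as.integer(pos_d) + 8L, text = "psoriasis",
               type = "Disease", id = "psoriasis"))
  doc <- annotated_document("103", doc$title, doc$abstract, m)
  st <- extract_statements(list(doc))
  expect_equal(nrow(st), 1L)

  # identifier resolving to >3 symbols is not considered
  doc4 <- make_doc("104", "A report.",
    "Expression of HLA was elevated in patients with psoriasis.",
    diseases = list("psoriasis"))
  p <- regexpr("HLA", doc4$text, fixed = TRUE)
  m4 <- rbind(doc4$mentions,
              data.frame(start = p - 1L, end = p + 2L, text = "HLA",
                         type = "Gene", id = "HLA-A;HLA-B;HLA-C;HLA-DRB1"))
  doc4 <- annotated_document("104", doc4$title, doc4$abstract, m4)
  expect_equal(nrow(extract_statements(list(doc4))), 0L)
  # but <= 3 candidate symbols yield one statement per symbol
  m5 <- m4
  m5$id[m5$type == "Gene"] <- "HLA-A;HLA-B"
  doc5 <- annotated_document("105", doc4$title, doc4$abstract, m5)
  expect_equal(sort(extract_statements(list(doc5))$gene),
               c("HLA-A", "HLA-B"))
})

test_that("opposite-sign qualifiers resolve by proximity or skip as ambiguous", {
  # qualifier adjacent to each gene: one statement each, correct signs
  doc <- make_doc("106", "A report.",
    paste("Expression of GA11 was elevated whereas expression of GB22",
          "was decreased in patients with psoriasis."),
    genes = list("GA11", "GB22"), diseases = list("psoriasis"))
  st <- extract_statements(list(doc), token_window = 3L)
  expect_equal(st$delta[st$gene == "GA11"], "increase")
  expect_equal(st$delta[st$gene == "GB22"], "decrease")
})

test_that("in-document disease abbreviations support tri-occurrence", {
  doc <- make_doc("107", "A report.",
    paste("Patients with atopic dermatitis (AD) were recruited.",
          "Expression of FLG was reduced in AD lesions."),
    genes = list("FLG"), diseases = list("atopic dermatitis"))
  st <- extract_statements(list(doc))
  expect_equal(nrow(st), 1L)
  expect_equal(st$disease, "atopic dermatitis")
  expect_equal(st$delta, "decrease")
})

test_that("extraction metrics follow the set-based definitions", {
  gold <- data.frame(pmid = as.character(1:4), gene = "G", disease = "D",
                     delta = "increase")
  pred <- rbind(gold[1:2, ],
                data.frame(pmid = "9", gene = "G", disease = "D",
                           delta = "decrease"))
  ev <- evaluate_extraction(pred, gold)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 1 / 2)
  expect_equal(ev$f1, 2 * (2/3) * (1/2) / (2/3 + 1/2))

  ev2 <- evaluate_extraction(gold, gold)
  expect_equal(c(ev2$precision, ev2$recall, ev2$f1), c(1, 1, 1))

  ev3 <- evaluate_extraction(gold[0, ], gold)
  expect_equal(ev3$precision, 1)
  expect_equal(ev3$recall, 0)
})

test_that("pubtator round-trips through write and read", {
  docs <- list(
    make_doc("201", "Title one.", "Expression of TP53 was elevated in lupus.",
             genes = list("TP53"), diseases = list("lupus")),
    make_doc("202", "Title two.", "Nothing to see here."))
  path <- tempfile(fileext = ".pubtator")
  write_pubtator(docs, path)
  back <- read_pubtator(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$text, docs[[1]]$text)
  expect_equal(back[[1]]$mentions$start, docs[[1]]$mentions$start)
  expect_equal(back[[2]]$mentions, empty_mentions())

  writeLines(c("1|t|T", "1|a|A", "1\t0\t1"), path)
  expect_error(read_pubtator(path), "malformed annotation line")
})

test_that("extraction is idempotent on its own evidence subset", {
  cfg <- synthetic_config(n_genes = 150, n_diseases = 2, distractor_frac = 0.4,
                          seed = 11)
  st <- simulate_study(cfg)
  first <- extract_statements(st$corpus, target_diseases = st$truth$diseases)
  # keep only documents that produced statements and re-extract
  keep <- vapply(st$corpus, function(d) d$pmid %in% first$pmid, logical(1))
  second <- extract_statements(st$corpus[keep],
                               target_diseases = st$truth$diseases)
  expect_equal(second[order(second$pmid, second$gene), ],
               first[order(first$pmid, first$gene), ],
               ignore_attr = TRUE)
})
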