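test_that("the bundled taxonomy loads with the documented structure", {
  tax <- load_taxonomy()
  expect_s3_class(tax, "mvskel_taxonomy")
  expect_equal(nrow(tax$codes), 53)
  expect_equal(tax$retained_l2, c("Spine", "Ribcage", "Whole-body"))
  expect_length(tax$retained_l3, 10)
  expect_false(anyDuplicated(tax$codes$code) > 0)
})

test_that("taxonomy validation rejects malformed inputs", {
  df <- data.frame(code = c("a", "a"), name = c("x", "y"),
                   l2 = c("Spine", "Spine"), l3 = c("Shape", "Shape"))
  expect_error(new_taxonomy(df), "duplicate")
  df2 <- data.frame(code = "a", name = "x", l2 = "Spleen", l3 = "Shape")
  expect_error(new_taxonomy(df2), "Spleen")
  expect_error(new_taxonomy(df2[0, ]), "nonempty")
  expect_error(new_taxonomy(data.frame(code = "a")), "missing column")
})

test_that("level-1 labeling is abnormal iff the code set is nonempty", {
  tax <- default_tax
  expect_equal(assign_l1("kyphosis", tax), "abnormal")
  expect_equal(assign_l1(character(0), tax), "normal")
  expect_equal(assign_l1(c("kyphosis", "rib-fusion", "syndactylism"), tax),
               "abnormal")
  expect_error(assign_l1("not-a-code", tax), "unknown abnormality code")
})

test_that("level-2 and level-3 mappings are set images under the taxonomy", {
  tax <- default_tax
  expect_equal(map_l2("kyphosis", tax), "Spine")
  expect_setequal(map_l2(c("kyphosis", "rib-fusion"), tax),
                  c("Spine", "Ribcage"))
  expect_equal(map_l2(character(0), tax), character(0))
  expect_equal(map_l3("caudal-truncation", tax), "Caudal")
  expect_setequal(map_l3(c("caudal-truncation", "thoracic-displacement"), tax),
                  c("Caudal", "Thoracic"))
  expect_equal(map_l3(character(0), tax), character(0))
})

test_that("specimen labels take the union over images and drop excluded subclasses", {
  tax <- default_tax
  l <- specimen_union(list("kyphosis", character(0)), "s1", tax)
  expect_equal(l$l1, "abnormal")
  expect_equal(l$l2_set, "Spine")

  l0 <- specimen_union(list(character(0), character(0)), "s2", tax)
  expect_equal(l0$l1, "normal")
  expect_length(l0$l2_set, 0)
  expect_true(all(l0$vector == 0))

  # Skull-only specimen stays level-1 abnormal with no retained bits
  ls <- specimen_union(list("skull-shape"), "s3", tax)
  expect_equal(ls$l1, "abnormal")
  expect_length(ls$l2_set, 0)
  expect_length(ls$l3_set, 0)
  expect_true(all(ls$vector == 0))

  expect_error(specimen_union(list(), "s4", tax), "no images")
})

test_that("label vectors have 13 slots and encode both level sets", {
  tax <- default_tax
  l <- specimen_union(list(c("kyphosis", "caudal-truncation")), "s1", tax)
  expect_length(l$vector, 13)
  expect_equal(sum(l$vector), 3)  # Spine + Caudal + Shape

  all_codes <- tax$codes$code[tax$codes$l2 %in% tax$retained_l2]
  sat <- specimen_union(list(all_codes), "s2", tax)
  expect_true(all(sat$vector[paste0("L2:", tax$retained_l2)] == 1))
})

test_that("encode/decode round-trips exactly for every possible label vector", {
  tax <- default_tax
  n2 <- length(tax$retained_l2)
  for (m2 in 0:(2^n2 - 1)) {
    l2_set <- tax$retained_l2[bitwAnd(m2, 2^(seq_len(n2) - 1)) > 0]
    for (m3 in 0:(2^10 - 1)) {
      l3_set <- tax$retained_l3[bitwAnd(m3, 2^(0:9)) > 0]
      v <- encode_label_vector(list(l2_set = l2_set, l3_set = l3_set), tax)
      d <- decode_label_vector(v, tax)
      if (!identical(d$l2_set, l2_set) || !identical(d$l3_set, l3_set)) {
        fail(sprintf("round trip failed at m2=%d m3=%d", m2, m3))
      }
    }
  }
  succeed()
})

test_that("adding a code never clears a label-vector bit", {
  tax <- default_tax
  set.seed(1)
  for (i in 1:50) {
    base <- sample(tax$codes$code, sample(0:5, 1))
    extra <- sample(setdiff(tax$codes$code, base), 1)
    v1 <- specimen_union(list(base), "a", tax)$vector
    v2 <- specimen_union(list(c(base, extra)), "a", tax)$vector
    expect_true(all(v2 >= v1))
  }
})

test_that("a set level-3 bit implies a set level-2 bit", {
  tax <- default_tax
  set.seed(2)
  for (i in 1:50) {
    codes <- sample(tax$codes$code, sample(1:6, 1))
    l <- specimen_union(list(codes), "a", tax)
    if (length(l$l3_set)) expect_gt(length(l$l2_set), 0)
  }
})

test_that("dataset summaries count abnormal specimens like a brute-force tally", {
  tax <- default_tax
  set.seed(3)
  labels <- lapply(1:40, function(i) {
    codes <- if (stats::runif(1) < 0.5) character(0)
             else sample(tax$codes$code, sample(1:3, 1))
    specimen_union(list(codes), paste0("s", i), tax)
  })
  s <- summarize_dataset(labels)
  brute <- sum(vapply(labels, function(l) length(l$codes) > 0, logical(1)))
  expect_equal(attr(s, "total_abnormal"), brute)
  expect_equal(attr(s, "total_abnormal") + attr(s, "total_normal"), 40)
  expect_true(all(diff(s$n) <= 0))  # sorted by descending count

  one <- summarize_dataset(list(specimen_union(list("kyphosis"), "x", tax)))
  expect_equal(nrow(one), 1)
  expect_equal(one$n, 1)
  expect_equal(one$l2_combination, "[Spine]")

  none <- summarize_dataset(lapply(1:3, function(i) {
    specimen_union(list(character(0)), paste0("n", i), tax)
  }))
  expect_equal(attr(none, "total_abnormal"), 0)
})

test_that("full-body view selection sums only the full-body rows", {
  counts <- data.frame(view = c("Full body-DV", "Full body-Lat", "Skull-DV"),
                       n_images = c(10, 20, 5),
                       n_abnormalities = c(1, 2, 7))
  sel <- select_fullbody_views(counts)
  expect_equal(sel$n_images, 30)
  expect_equal(sel$n_abnormalities, 3)
  expect_error(select_fullbody_views(data.frame(view = "x")), "missing column")
})
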