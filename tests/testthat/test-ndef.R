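test_that("MIME type mapping is exact", {
  expect_identical(mime_type_for("manchester"), "text/owl-manchester")
  expect_identical(mime_type_for("functional"), "text/owl-functional")
  expect_identical(mime_type_for("rdfxml"), "application/rdf+xml")
  expect_identical(mime_type_for("owlxml"), "application/owl+xml")
  expect_identical(mime_type_for("turtle"), "text/turtle")
  expect_error(mime_type_for("krss"), "unsupported")
})

test_that("every codec round-trips arbitrary binary payloads", {
  expect_identical(compress_payload(charToRaw("abc"), "none"), charToRaw("abc"))
  set.seed(31)
  for (i in 1:10) {
    data <- as.raw(sample(0:255, sample(c(0, 1, 17, 333, 2048), 1L), replace = TRUE))
    for (cd in c("none", "deflate", "gzip", "lzma")) {
      z <- compress_payload(data, cd)
      expect_identical(decompress_payload(z, cd), data,
                       label = paste(cd, length(data)))
    }
  }
})

test_that("deflate output is the gzip stream minus framing overhead", {
  kg <- build_demo_kg()
  docs <- lapply(generate_corpus(seed = 5, kg = kg),
                 serialize_annotation, syntax = "functional")
  dfl <- vapply(docs, function(d) length(compress_payload(charToRaw(d), "deflate")), numeric(1))
  gz <- vapply(docs, function(d) length(compress_payload(charToRaw(d), "gzip")), numeric(1))
  expect_true(all(dfl < gz))        # gzip adds header and trailer bytes
  expect_true(all(gz - dfl == 12))  # 18 B gzip framing vs 6 B zlib framing
})

test_that("record headers respect the wire-format invariants", {
  # short-record boundary: SR iff payload < 256 bytes
  short <- ndef_message(ndef_record(2L, "text/owl-manchester", as.raw(rep(1L, 255L))))
  long <- ndef_message(ndef_record(2L, "text/owl-manchester", as.raw(rep(1L, 256L))))
  sbytes <- encode_ndef(short); lbytes <- encode_ndef(long)
  expect_true(bitwAnd(as.integer(sbytes[1L]), 16L) > 0L)   # SR set
  expect_false(bitwAnd(as.integer(lbytes[1L]), 16L) > 0L)  # long form
  expect_identical(length(lbytes) - length(sbytes), 4L)    # 4-byte length + 1 payload byte - 1
  expect_identical(decode_ndef(lbytes)$records[[1L]]$payload, as.raw(rep(1L, 256L)))

  # MB on first record only, ME on last; IL only where an id is present
  msg <- ndef_message(list(ndef_record(2L, "text/plain", charToRaw("a"), id = "tag-1"),
                           ndef_record(1L, "T", charToRaw("b"))))
  bytes <- encode_ndef(msg)
  back <- decode_ndef(bytes)
  expect_length(back$records, 2L)
  expect_identical(rawToChar(back$records[[1L]]$id), "tag-1")
  expect_identical(back$records[[2L]]$id, raw())
  flags1 <- as.integer(bytes[1L])
  expect_true(bitwAnd(flags1, 128L) > 0L && bitwAnd(flags1, 64L) == 0L)

  # structural validation
  expect_error(ndef_record(0L, "x"), "TNF=0")
  expect_error(ndef_record(5L, "x"), "TNF=5")
  expect_error(decode_ndef(bytes[-length(bytes)]), "truncated")
  bad <- bytes; bad[1L] <- as.raw(bitwAnd(as.integer(bad[1L]), 127L))  # clear MB
  expect_error(decode_ndef(bad), "lacks MB")
  expect_error(decode_ndef(c(bytes, as.raw(0L))), "trailing")
})

test_that("annotation messages encode and decode byte-exactly", {
  kg <- build_demo_kg()
  corpus <- generate_corpus(seed = 17, kg = kg)
  set.seed(18)
  for (prof in corpus[sample(seq_along(corpus), 6L)]) {
    sx <- sample(c("manchester", "functional"), 1L)
    cd <- sample(c("none", "deflate", "gzip", "lzma"), 1L)
    doc <- serialize_annotation(prof, sx, kg$kg_iri)
    task <- paste0(prof$category, "s")
    bytes <- encode_annotation_message(doc, sx, cd, kg$kg_iri, task)
    # re-encoding is deterministic
    expect_identical(encode_annotation_message(doc, sx, cd, kg$kg_iri, task), bytes)
    got <- decode_message(bytes)
    expect_length(got, 1L)
    expect_identical(got[[1L]]$text, doc)
    expect_identical(got[[1L]]$codec, cd)
    expect_identical(rawToChar(got[[1L]]$record$id), paste0(kg$kg_iri, "#", task))
  }
})

test_that("a tag-filling annotation uses the long-record form", {
  payload <- paste(rep("x", 848L), collapse = "")
  bytes <- encode_annotation_message(payload, "manchester", "none")
  expect_false(bitwAnd(as.integer(bytes[1L]), 16L) > 0L)  # SR = 0
  expect_identical(nchar(decode_message(bytes)[[1L]]$text), 848L)
})

test_that("non-OWL records pass through untouched and ids can be filtered", {
  kg <- build_demo_kg()
  doc <- serialize_annotation(worked_example("example1", kg)$patient,
                              "manchester", kg$kg_iri)
  owl <- ndef_record(2L, paste0("text/owl-manchester;codec=deflate"),
                     compress_payload(charToRaw(doc), "deflate"),
                     id = paste0(kg$kg_iri, "#patients"))
  wellknown <- ndef_record(1L, "U", charToRaw("example.org"))
  out <- decode_message(encode_ndef(ndef_message(list(owl, wellknown))))
  expect_length(out, 2L)
  expect_identical(out[[1L]]$text, doc)
  expect_null(out[[2L]]$text)  # legacy record left undecoded
  expect_identical(out[[2L]]$record$payload, charToRaw("example.org"))

  filtered <- decode_message(encode_ndef(ndef_message(list(owl, wellknown))),
                             id_prefix = paste0(kg$kg_iri, "#patients"))
  expect_length(filtered, 1L)
  expect_identical(filtered[[1L]]$text, doc)

  bad <- ndef_record(2L, "text/owl-manchester;codec=snappy", charToRaw("x"))
  expect_error(decode_message(encode_ndef(ndef_message(list(bad)))),
               "unknown codec")
})

test_that("tag capacity checks compare encoded length", {
  kg <- build_demo_kg()
  doc <- serialize_annotation(worked_example("example1", kg)$patient,
                              "functional", kg$kg_iri)
  msg <- encode_annotation_message(doc, "functional", "deflate", kg$kg_iri, "patients")
  expect_true(fits_tag(msg, 888))   # NTAG216-sized tag
  expect_false(fits_tag(as.raw(rep(0L, 889L)), 888))
  expect_true(fits_tag(raw(), 888))
})
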