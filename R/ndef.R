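#' MIME types for OWL serialization syntaxes
#'
#' Standard MIME type carried in the Type field of a MIME-typed (TNF = 2)
#' NDEF record to identify the annotation serialization in the payload.
#'
#' @param syntax One of `"rdfxml"`, `"owlxml"`, `"functional"`,
#'   `"manchester"`, `"turtle"`.
#' @return A MIME type string.
#' @examples
#' mime_type_for("manchester")
#' @export
mime_type_for <- function(syntax) {
  map <- c(rdfxml = "application/rdf+xml",
           owlxml = "application/owl+xml",
           functional = "text/owl-functional",
           manchester = "text/owl-manchester",
           turtle = "text/turtle")
  if (!is.character(syntax) || length(syntax) != 1L || !syntax %in% names(map))
    stop(sprintf("unsupported OWL syntax '%s'", paste(syntax, collapse = ",")),
         call. = FALSE)
  unname(map[syntax])
}

SUPPORTED_CODECS <- c("none", "deflate", "gzip", "lzma")

# ---- compression codecs --------------------------------------------------
#
# deflate = the zlib (RFC 1950) framing of the raw DEFLATE stream, 6 bytes
# of overhead; gzip = the RFC 1952 framing of the same stream, 18 bytes of
# overhead (10-byte header + CRC32 + length trailer); lzma = the xz
# container. All are produced through R's built-in zlib/liblzma bindings;
# the gzip member is re-framed here with a real CRC32 so external tools
# (`gzip -t`) accept it.

crc32_tab <- local({
  tb <- integer(256L)
  for (i in 0:255) {
    cr <- i
    for (k in 1:8)
      cr <- if (bitwAnd(cr, 1L) == 1L)
        bitwXor(bitwShiftR(cr, 1L), -306674912L)  # 0xEDB88320
      else bitwShiftR(cr, 1L)
    tb[i + 1L] <- cr
  }
  tb
})

crc32 <- function(x) {
  cr <- -1L
  for (b in as.integer(x))
    cr <- bitwXor(bitwShiftR(cr, 8L), crc32_tab[bitwAnd(bitwXor(cr, b), 255L) + 1L])
  bitwXor(cr, -1L)
}

uint32_le <- function(v) {
  v <- as.numeric(v); if (v < 0) v <- v + 2^32
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
}

le_uint32 <- function(r) {
  sum(as.numeric(r) * c(1, 256, 65536, 16777216))
}

#' Compress / decompress a payload
#'
#' `codec` is one of `"none"` (identity), `"deflate"` (zlib framing),
#' `"gzip"` (gzip framing of the same stream) or `"lzma"` (xz container).
#' Decompression inverts compression exactly for every codec and any
#' binary payload.
#'
#' @param data A raw vector (or a string, converted with [charToRaw()]).
#' @param codec Codec name.
#' @return A raw vector.
#' @export
compress_payload <- function(data, codec = SUPPORTED_CODECS) {
  codec <- match.arg(codec)
  if (is.character(data)) data <- charToRaw(paste(data, collapse = "\n"))
  stopifnot(is.raw(data))
  switch(codec,
    none = data,
    deflate = memCompress(data, type = "gzip"),  # zlib framing
    gzip = {
      z <- memCompress(data, type = "gzip")
      stream <- z[seq.int(3L, length(z) - 4L)]   # strip zlib header + adler32
      c(as.raw(c(0x1f, 0x8b, 0x08, 0, 0, 0, 0, 0, 0, 0xff)),
        stream, uint32_le(crc32(data)), uint32_le(length(data) %% 2^32))
    },
    lzma = memCompress(data, type = "xz"))
}

#' @rdname compress_payload
#' @export
decompress_payload <- function(data, codec = SUPPORTED_CODECS) {
  codec <- match.arg(codec)
  stopifnot(is.raw(data))
  switch(codec,
    none = data,
    deflate = memDecompress(data, type = "gzip"),
    gzip = {
      if (length(data) < 18L || data[1L] != as.raw(0x1f) || data[2L] != as.raw(0x8b))
        stop("not a gzip stream", call. = FALSE)
      # R's inflate accepts the gzip framing directly and checks the CRC
      memDecompress(data, type = "gzip")
    },
    lzma = memDecompress(data, type = "xz"))
}

#' NDEF records and messages
#'
#' An NDEF record per the NFC Forum layout: a flags byte
#' (MB, ME, CF, SR, IL and the 3-bit TNF), a 1-byte type length, a 1-byte
#' (short record) or 4-byte big-endian payload length, an optional 1-byte
#' id length, then type, id and payload. TNF values follow the standard
#' registry (0 empty, 1 well-known, 2 MIME, 3 URI, 4 external, 5 unknown,
#' 6 unchanged, 7 reserved). The short-record form is chosen
#' automatically for payloads under 256 bytes.
#'
#' @param tnf Integer 0–7.
#' @param type Raw vector or string (record type, e.g. a MIME type).
#' @param payload Raw vector.
#' @param id Raw vector or string; only the first record of a message
#'   carries an id.
#' @param chunked Logical; chunk-flag (CF) records are accepted on decode
#'   but not produced.
#' @return `ndef_record()` returns an object of class `ndef_record`;
#'   `ndef_message()` wraps an ordered list of records.
#' @export
ndef_record <- function(tnf, type = raw(), payload = raw(), id = raw(),
                        chunked = FALSE) {
  stopifnot(is.numeric(tnf), tnf == round(tnf), tnf >= 0, tnf <= 7)
  if (is.character(type)) type <- charToRaw(type)
  if (is.character(id)) id <- charToRaw(id)
  stopifnot(is.raw(type), is.raw(payload), is.raw(id))
  if (tnf == 0L && (length(type) || length(payload) || length(id)))
    stop("an empty (TNF=0) record cannot carry type, id or payload", call. = FALSE)
  if (tnf == 5L && length(type))
    stop("an unknown-type (TNF=5) record must have zero type length", call. = FALSE)
  if (length(type) > 255L) stop("record type longer than 255 bytes", call. = FALSE)
  if (length(id) > 255L) stop("record id longer than 255 bytes", call. = FALSE)
  if (length(payload) >= 2^32) stop("payload exceeds the 4 GiB format limit", call. = FALSE)
  structure(list(tnf = as.integer(tnf), type = type, id = id,
                 payload = payload, chunked = isTRUE(chunked)),
            class = "ndef_record")
}

#' @rdname ndef_record
#' @param records List of `ndef_record`.
#' @export
ndef_message <- function(records) {
  if (inherits(records, "ndef_record")) records <- list(records)
  stopifnot(is.list(records), length(records) >= 1L,
            all(vapply(records, inherits, logical(1L), "ndef_record")))
  structure(list(records = records), class = "ndef_message")
}

#' @export
print.ndef_record <- function(x, ...) {
  cat(sprintf("<ndef_record> TNF=%d type=%s id=%s payload=%d B%s\n",
              x$tnf, rawToChar(x$type), rawToChar(x$id), length(x$payload),
              if (x$chunked) " (chunked)" else ""))
  invisible(x)
}

#' @export
print.ndef_message <- function(x, ...) {
  cat(sprintf("<ndef_message> %d record(s), %d B encoded\n",
              length(x$records), length(encode_ndef(x))))
  for (r in x$records) print(r)
  invisible(x)
}

#' Encode / decode binary NDEF
#'
#' [encode_ndef()] produces the byte-exact NFC Forum wire form of a
#' message: MB set on the first record, ME on the last, SR chosen per
#' record for payloads under 256 bytes, IL set only when an id is
#' present. [decode_ndef()] inverts it and validates the header flags,
#' rejecting truncated or malformed input.
#'
#' @param msg An `ndef_message`.
#' @param raw_bytes A raw vector.
#' @return A raw vector, resp. an `ndef_message`.
#' @export
encode_ndef <- function(msg) {
  stopifnot(inherits(msg, "ndef_message"))
  n <- length(msg$records)
  out <- raw()
  for (i in seq_len(n)) {
    r <- msg$records[[i]]
    sr <- length(r$payload) < 256L
    il <- length(r$id) > 0L
    flags <- r$tnf +
      (if (il) 8L else 0L) + (if (sr) 16L else 0L) +
      (if (r$chunked) 32L else 0L) +
      (if (i == n) 64L else 0L) + (if (i == 1L) 128L else 0L)
    hdr <- c(as.raw(flags), as.raw(length(r$type)))
    plen <- if (sr) as.raw(length(r$payload)) else rev(uint32_le(length(r$payload)))
    hdr <- c(hdr, plen)
    if (il) hdr <- c(hdr, as.raw(length(r$id)))
    out <- c(out, hdr, r$type, r$id, r$payload)
  }
  out
}

#' @rdname encode_ndef
#' @export
decode_ndef <- function(raw_bytes) {
  stopifnot(is.raw(raw_bytes), length(raw_bytes) >= 3L)
  i <- 1L; n <- length(raw_bytes)
  need <- function(k) {
    if (k == 0L) return(raw())
    if (i + k - 1L > n) stop("truncated NDEF message", call. = FALSE)
    out <- raw_bytes[seq.int(i, i + k - 1L)]
    i <<- i + k
    out
  }
  records <- list(); first <- TRUE; ended <- FALSE
  while (!ended) {
    if (i > n) stop("malformed NDEF: message ended without ME flag", call. = FALSE)
    flags <- as.integer(need(1L))
    mb <- bitwAnd(flags, 128L) > 0L; me <- bitwAnd(flags, 64L) > 0L
    cf <- bitwAnd(flags, 32L) > 0L; sr <- bitwAnd(flags, 16L) > 0L
    il <- bitwAnd(flags, 8L) > 0L; tnf <- bitwAnd(flags, 7L)
    if (first && !mb) stop("malformed NDEF header: first record lacks MB", call. = FALSE)
    if (!first && mb) stop("malformed NDEF header: MB set on a later record", call. = FALSE)
    tlen <- as.integer(need(1L))
    plen <- if (sr) as.integer(need(1L)) else le_uint32(rev(need(4L)))
    ilen <- if (il) as.integer(need(1L)) else 0L
    type <- need(tlen); id <- need(ilen); payload <- need(plen)
    records <- c(records, list(ndef_record(tnf, type, payload, id, chunked = cf)))
    first <- FALSE; ended <- me
  }
  if (i <= n) stop("trailing bytes after final NDEF record", call. = FALSE)
  ndef_message(records)
}

#' Encode an annotation into a tag message
#'
#' Builds the single-record NDEF message stored on an emulated tag: a
#' MIME-typed (TNF = 2) record whose Type field is the OWL MIME type of
#' the chosen syntax with a `;codec=` parameter naming the compression,
#' whose ID is `"<kg-iri>#<task>"` (so readers can filter tags by task),
#' and whose payload is the compressed annotation document.
#'
#' @param annotation Annotation document text (string or lines).
#' @param syntax OWL serialization syntax, see [mime_type_for()].
#' @param codec Compression codec, see [compress_payload()].
#' @param kg_iri Reference knowledge-graph IRI.
#' @param task Task selector, e.g. `"patients"`, `"caregivers"`,
#'   `"treatments"`.
#' @return A raw vector (the encoded message).
#' @export
encode_annotation_message <- function(annotation, syntax = "manchester",
                                      codec = "none",
                                      kg_iri = "http://example.org/sh",
                                      task = "patients") {
  mime <- mime_type_for(syntax)
  codec <- match.arg(codec, SUPPORTED_CODECS)
  payload <- compress_payload(charToRaw(paste(annotation, collapse = "\n")), codec)
  rec <- ndef_record(2L, type = paste0(mime, ";codec=", codec),
                     payload = payload, id = paste0(kg_iri, "#", task))
  encode_ndef(ndef_message(list(rec)))
}

OWL_MIME_TYPES <- c("application/rdf+xml", "application/owl+xml",
                    "text/owl-functional", "text/owl-manchester", "text/turtle")

#' Decode a tag message
#'
#' Parses a binary NDEF message and decompresses every MIME-typed record
#' carrying a recognized OWL MIME type back to annotation text; records
#' of any other TNF or type are passed through untouched, preserving
#' compatibility with legacy NFC content. An optional id prefix filter
#' selects records by task (e.g. only `"<kg-iri>#patients"` tags).
#'
#' @param raw_bytes A raw vector.
#' @param id_prefix Optional filter: keep only records whose id starts
#'   with this string.
#' @return A list with one element per kept record:
#'   `list(record =, text = decoded text or NULL, mime =, codec =)`.
#' @export
decode_message <- function(raw_bytes, id_prefix = NULL) {
  msg <- decode_ndef(raw_bytes)
  out <- list()
  for (rec in msg$records) {
    if (!is.null(id_prefix) && !startsWith(rawToChar(rec$id), id_prefix)) next
    entry <- list(record = rec, text = NULL, mime = NULL, codec = NULL)
    if (rec$tnf == 2L) {
      type <- rawToChar(rec$type)
      parts <- strsplit(type, ";", fixed = TRUE)[[1L]]
      mime <- trimws(parts[1L])
      if (mime %in% OWL_MIME_TYPES) {
        codec <- "none"
        for (p in parts[-1L]) {
          kv <- strsplit(trimws(p), "=", fixed = TRUE)[[1L]]
          if (length(kv) == 2L && kv[1L] == "codec") codec <- kv[2L]
        }
        if (!codec %in% SUPPORTED_CODECS)
          stop(sprintf("unknown codec parameter '%s'", codec), call. = FALSE)
        entry$text <- rawToChar(decompress_payload(rec$payload, codec))
        entry$mime <- mime
        entry$codec <- codec
      }
    }
    out <- c(out, list(entry))
  }
  out
}

#' Does a message fit a tag?
#'
#' @param message Encoded message (raw vector).
#' @param capacity Tag memory in bytes (e.g. 888 for an NXP NTAG216).
#' @return Logical.
#' @export
fits_tag <- function(message, capacity) {
  stopifnot(is.raw(message), is.numeric(capacity), capacity > 0)
  length(message) <= capacity
}
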