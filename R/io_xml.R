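# Generic XML ECG dialect: a root element carrying sampling-rate and gain
# attributes with one child element per lead holding whitespace-separated
# values (ADU when a gain is declared, mV otherwise). Vendor dialects are
# extension points, not claims about any specific schema.
#
#   <ecg sampling_rate="500" gain="1000">
#     <lead name="I">12 18 7 ...</lead>
#     ...
#   </ecg>

xmlecg_write <- function(record, path, gain = NULL) {
  gain <- gain %||% record$gain_adu_per_mv
  doc <- xml2::xml_new_root("ecg", sampling_rate = format(record$fs),
                            gain = if (!is.null(gain)) format(gain))
  vals <- if (!is.null(gain)) round(record$signal * gain) else record$signal
  for (i in seq_len(nrow(record$signal))) {
    node <- xml2::xml_add_child(doc, "lead", name = record$lead_names[i])
    xml2::xml_text(node) <- paste(format(vals[i, ], trim = TRUE, scientific = FALSE),
                                  collapse = " ")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

xmlecg_read <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) ecg_stop("ReadError", "malformed XML: %s",
                                               conditionMessage(e)))
  root <- doc
  fs <- as.numeric(xml2::xml_attr(root, "sampling_rate"))
  if (is.na(fs)) fs <- as.numeric(xml2::xml_attr(root, "fs"))
  gain <- as.numeric(xml2::xml_attr(root, "gain"))
  leads <- xml2::xml_find_all(root, ".//lead")
  if (!length(leads)) ecg_stop("ReadError", "no <lead> elements in XML file")
  names <- xml2::xml_attr(leads, "name")
  rows <- lapply(leads, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(xml2::xml_text(l)), "\\s+")[[1]]))
    if (anyNA(v)) ecg_stop("ReadError", "non-numeric payload in XML lead")
    v
  })
  n <- unique(vapply(rows, length, integer(1)))
  if (length(n) != 1) ecg_stop("ReadError", "leads of unequal length in XML file")
  sig <- do.call(rbind, rows)
  if (!is.na(gain) && gain > 0) sig <- sig / gain
  list(signal = sig, fs = if (is.na(fs)) NULL else fs,
       gain = if (is.na(gain)) NULL else gain,
       lead_names = if (anyNA(names)) NULL else names)
}
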