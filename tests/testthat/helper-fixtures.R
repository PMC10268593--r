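# Shared in-code fixtures.

# Minimal exon feature table for a single transcript, in read_gff3() layout.
mk_exons <- function(tid, coords, scaffold = "s1", strand = "+") {
  do.call(rbind, lapply(coords, function(se) {
    data.frame(scaffold = scaffold, source = "x", type = "exon",
               start = se[1], end = se[2], score = NA_real_, strand = strand,
               phase = ".", ID = NA_character_, Parent = tid,
               attributes = paste0("Parent=", tid), stringsAsFactors = FALSE)
  }))
}
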