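count_sections <- function(html, class) {
  sum(grepl(sprintf('<section class="%s"', class), html, fixed = TRUE))
}
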