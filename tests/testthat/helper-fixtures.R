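# fixtures built in code: small trees and tables used across tests

tree_from_text <- function(txt) ape::read.tree(text = txt)

balanced3 <- function() tree_from_text("((A:1,B:1):1,C:2);")

write_table_fixture <- function(lines, ext = ".csv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

# 4-species, 2-toxin table: X present in 2 species, Y in 1
toy_presence_table <- function() {
  tibble::tibble(species = c("A", "B", "C", "D"),
                 X = c(0.5, 0.2, 0, 0),
                 Y = c(0.3, 0, 0, 0))
}

trait_of <- function(...) {
  v <- c(...)
  tibble::tibble(species = names(v), value = unname(v))
}
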