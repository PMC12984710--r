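.onLoad <- function(libname, pkgname) {
  register_backbone("small_mlp", small_mlp)
  register_backbone("softmax_linear", function(input_size = 16L, l2 = 1e-4) {
    small_mlp(input_size = input_size, hidden = 0L, l2 = l2)
  })
}
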