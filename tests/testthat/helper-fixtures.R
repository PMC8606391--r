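# Shared test objects: a moderate reference material, small geometries and
# ring specimens. Everything is built in code at test time.

test_stack <- function() {
  material_stack(
    layer_material("mucosa", c_kpa = 5, a_dimless = 1.2),
    layer_material("muscularis", c_kpa = 15, a_dimless = 1.0)
  )
}

# uniform cylinder: no flare, no taper -> every station is the same ring
uniform_sleeve <- function(size_fr = 27, length_mm = 150, spacing_mm = 2) {
  build_sleeve(
    bougie_spec(size_fr, length_mm = length_mm),
    flare = 1, end_taper_length_mm = 0, spacing_mm = spacing_mm
  )
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), rel_tol)
}
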