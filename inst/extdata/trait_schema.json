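{
  "traits": [
    {
      "code": "A",
      "name": "feeding",
      "kind": "nominal",
      "categories": ["a", "b", "c", "d", "e", "f", "g"]
    },
    {
      "code": "B",
      "name": "maximum_longevity",
      "kind": "ordinal",
      "categories": ["1", "2", "3", "4", "5"]
    },
    {
      "code": "C",
      "name": "coloniality",
      "kind": "nominal",
      "categories": ["a", "b"]
    },
    {
      "code": "D",
      "name": "morphological_form",
      "kind": "nominal",
      "categories": ["a", "b", "c", "d", "e", "f", "g", "h", "i", "j", "k", "l"]
    },
    {
      "code": "E",
      "name": "carbon_storage",
      "kind": "nominal",
      "categories": ["a", "b", "c"]
    },
    {
      "code": "F",
      "name": "energetic_resource",
      "kind": "nominal",
      "categories": ["a", "b", "c"]
    },
    {
      "code": "G",
      "name": "height",
      "kind": "ordinal",
      "categories": ["1", "2", "3", "4", "5"]
    },
    {
      "code": "H",
      "name": "growth_rate",
      "kind": "ordinal",
      "categories": ["1", "2", "3", "4", "5"]
    },
    {
      "code": "I",
      "name": "calcification",
      "kind": "nominal",
      "categories": ["a", "b"]
    },
    {
      "code": "J",
      "name": "motility",
      "kind": "nominal",
      "categories": ["a", "b"]
    }
  ]
}
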