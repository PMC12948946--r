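{
  "fermented": ["fermented", "sour", "vinegar", "alcoholic", "lactic_acid"],
  "dairy": ["yoghurt", "buttermilk", "cheese", "butter"],
  "grain_cereal": ["grain", "bread", "porridge", "wholegrain", "yeasty"],
  "fruity": ["apple", "citrus", "berry", "dried_fruit", "banana"],
  "vegetal": ["grassy", "hay", "cucumber", "leafy"],
  "sweet": ["honey", "caramel", "vanilla", "malty"],
  "nutty": ["nutty", "roasted", "almond"],
  "earthy": ["earthy", "mushroom", "musty", "soil"],
  "spicy": ["spicy", "clove", "pepper"],
  "floral": ["floral", "rose", "elderflower"],
  "chemical": ["chemical", "solvent", "nail_polish", "sulphur", "glue"],
  "animal": ["animal", "barnyard", "sweaty", "body_odour"],
  "other": ["ocean", "smoky", "metallic", "soapy", "woody", "leather", "buttery_popcorn"]
}
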