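disorder	pt
hypokalemia	hypokalaemia
hypokalemia	blood potassium decreased
hyperkalemia	hyperkalaemia
hyperkalemia	blood potassium increased
hyponatremia	hyponatraemia
hyponatremia	blood sodium decreased
hypernatremia	hypernatraemia
hypernatremia	blood sodium increased
hypocalcemia	hypocalcaemia
hypocalcemia	blood calcium decreased
hypercalcemia	hypercalcaemia
hypercalcemia	blood calcium increased
hypomagnesemia	hypomagnesaemia
hypomagnesemia	blood magnesium decreased
hypermagnesemia	hypermagnesaemia
hypermagnesemia	blood magnesium increased
hypophosphatemia	hypophosphataemia
hypophosphatemia	blood phosphorus decreased
hyperphosphatemia	hyperphosphataemia
hyperphosphatemia	blood phosphorus increased
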