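PREFIX dc: <http://purl.org/dc/elements/1.1/>
PREFIX ro: <http://www.obofoundry.org/ro/ro.owl#>
PREFIX obo: <http://purl.obolibrary.org/obo/>
PREFIX go: <http://purl.org/obo/owl/GO#>
PREFIX k: <http://krauthammerlab.med.yale.edu/>
SELECT (count (distinct ?repA) as ?apopcount) (count (distinct ?repA)/
               count (distinct ?repB) as ?ratio) ?sampName
WHERE {
   ?ds dc:title "Methylation Relative" .
   ?ds2 dc:title "AZA Pre-Post Treatment Ratios" .
   ?obs ro:part_of ?ds .
   # IAO_0000004 = 'has measurement value'
   ?obs obo:IAO_0000004 ?obsVal .
   ?obs obo:IAO_0000136 ?repA .
   ?obs obo:IAO_0000136 ?samp .
   # OBI_0100060 = 'cell culture'
   ?samp a obo:OBI_0100060 .
   ?samp dc:title ?sampName .
   # go:0006915 = 'apoptosis'
   ?repA ro:participates_in go:0006915 .
   ?obs2 obo:IAO_0000136 ?repA .
   ?obs2 ro:part_of ?ds2 .
   ?obs2 obo:IAO_0000004 ?obsVal2 .
   ?obs2 obo:IAO_0000136 ?samp .
   ?dsB dc:title "Methylation Relative" .
   ?dsB2 dc:title "AZA Pre-Post Treatment Ratios" .
   ?obsB ro:part_of ?dsB .
   ?obsB obo:IAO_0000004 ?obsBVal .
   ?obsB obo:IAO_0000136 ?repB .
   ?obsB obo:IAO_0000136 ?sampB .
   ?sampB a obo:OBI_0100060 .
   ?sampB dc:title ?sampName .
   # go:0008283 = 'cell proliferation'
   ?repB ro:participates_in go:0008283 .
   ?obs2B obo:IAO_0000136 ?repB .
   ?obs2B ro:part_of ?dsB2 .
   ?obs2B obo:IAO_0000004 ?obsBVal2 .
   ?obs2B obo:IAO_0000136 ?sampB .
   FILTER ( ?obsVal > 2) .
   FILTER ( ?obsVal2 > 1) .
   FILTER ( ?obsBVal > 2) .
   FILTER ( ?obsBVal2 > 1) .
}
GROUP BY ?sampName
ORDER BY ?sampName
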