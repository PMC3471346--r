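PREFIX dc: <http://purl.org/dc/elements/1.1/>
PREFIX ro: <http://www.obofoundry.org/ro/ro.owl#>
PREFIX obo: <http://purl.obolibrary.org/obo/>
PREFIX k: <http://krauthammerlab.med.yale.edu/>
SELECT distinct ?rep ?tf ?samp ?obsVal ?obsVal2
WHERE {
   ?ds dc:title "Methylation Relative" .
   ?ds2 dc:title "AZA Pre-Post Treatment Ratios" .
   ?obs ro:part_of ?ds .
   ?obs obo:IAO_0000004 ?obsVal .
   ?obs obo:IAO_0000136 ?rep .
   ?obs obo:IAO_0000136 ?samp .
   ?samp a obo:OBI_0100060 .
   ?rep k:corresponds_to ?tf .
   ?obs2 obo:IAO_0000136 ?rep .
   ?obs2 ro:part_of ?ds2 .
   ?obs2 obo:IAO_0000004 ?obsVal2 .
   ?obs2 obo:IAO_0000136 ?samp .
   FILTER (?obsVal > 2) .
   FILTER (?obsVal2 > 0.5)
}
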