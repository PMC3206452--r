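<?xml version="1.0" encoding="UTF-8"?>
<!-- SCF convergence summary: total energy in hartree. -->
<template id="scfdone" pattern="\s*SCF Done:.*" section="calculation">
  <record id="scf">\s*SCF Done:\s+E\({X, g:scfmethod}\) =\s+{1F, g:scfenergy}\s+A\.U\. after\s+{1I, g:cycles} cycles.*</record>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:scfenergy']" value="cc:hfenergy"/>
  <transform process="addUnits" xpath=".//cml:scalar[@dictRef='cc:hfenergy']" value="nonsi:hartree"/>
</template>
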