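<?xml version="1.0" encoding="UTF-8"?>
<template id="nucrep" pattern="\s*nuclear repulsion energy\s+.*" section="calculation">
  <record id="nucrep">\s*nuclear repulsion energy\s+{1F, g:nucrep}\s+Hartrees\..*</record>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:nucrep']" value="cc:nucrepener"/>
  <transform process="addUnits" xpath=".//cml:scalar[@dictRef='cc:nucrepener']" value="nonsi:hartree"/>
</template>
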