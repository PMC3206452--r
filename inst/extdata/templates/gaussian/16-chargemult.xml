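<?xml version="1.0" encoding="UTF-8"?>
<template id="chargemult" pattern="\s*Charge =.*" section="initialization">
  <record id="chargemult">\s*Charge =\s*{1I, g:charge}\s+Multiplicity =\s*{1I, g:multiplicity}\s*</record>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:charge']" value="cc:formalCharge"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:multiplicity']" value="cc:multiplicity"/>
</template>
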