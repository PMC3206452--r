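<?xml version="1.0" encoding="UTF-8"?>
<!-- Harmonic frequency table (link 716), three modes per column block;
     per-block arrays are stitched into one array per quantity. -->
<template id="l716.freq" pattern="\s*Harmonic frequencies \(cm\*\*-1\).*"
          section="finalization">
  <record id="freq" repeat="*">\s*Frequencies --{1_3F, g:freq}\s*</record>
  <record id="redmass" repeat="*">\s*Red\. masses --{1_3F, g:redmass}\s*</record>
  <record id="irint" repeat="*">\s*IR Inten\s+--{1_3F, g:irint}\s*</record>
  <transform process="addDictRef" xpath=".//cml:array[@cmlx:temp='g:freq']" value="cc:frequency"/>
  <transform process="addDictRef" xpath=".//cml:array[@cmlx:temp='g:redmass']" value="cc:redmass"/>
  <transform process="addDictRef" xpath=".//cml:array[@cmlx:temp='g:irint']" value="cc:irintensity"/>
  <transform process="joinArrays" xpath=".//cml:array[@dictRef='cc:frequency']"/>
  <transform process="joinArrays" xpath=".//cml:array[@dictRef='cc:redmass']"/>
  <transform process="joinArrays" xpath=".//cml:array[@dictRef='cc:irintensity']"/>
</template>
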